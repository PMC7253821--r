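# Closed-form moments of the zero-clipped normal max(0, N(mu, sigma^2)),
# used as the independent oracle for noisy-Poisson Fano factors when rates
# are clipped at zero.
clipped_normal_moments <- function(mu, sigma) {
  a <- mu / sigma
  m1 <- mu * pnorm(a) + sigma * dnorm(a)
  m2 <- (mu^2 + sigma^2) * pnorm(a) + mu * sigma * dnorm(a)
  list(mean = m1, var = m2 - m1^2)
}

# Expected count Fano factor over a window of w_s seconds for a Poisson
# process whose rate is lambda plus a clipped Gaussian per-trial offset:
# counts N | L ~ Poisson(L * w_s), L = max(0, lambda + eta).
expected_noisy_fano <- function(lambda, sigma, w_s) {
  m <- clipped_normal_moments(lambda, sigma)
  (m$mean * w_s + m$var * w_s^2) / (m$mean * w_s)
}

# Small manually assembled SDF matrix for hand-computable statistics.
manual_sdf_matrix <- function(values, dt = 1, sigma = 30) {
  structure(list(values = values,
                 time_grid = seq_len(ncol(values)) * dt,
                 kernel = kernel_spec(sigma = sigma, dt = dt),
                 n_trials = nrow(values)),
            class = "sdf_matrix")
}

# Trial set built directly from lists of spike times.
manual_trial_set <- function(times_list, duration = 1000, align_event = 0) {
  trains <- lapply(times_list, spike_train, duration = duration)
  new_trial_set(trains, align_event = align_event)
}
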
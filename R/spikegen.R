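#' Poisson probability mass function
#'
#' Probability of observing `count` spikes when the expected number of
#' occurrences in the window is `mu`:
#' \eqn{P(k; \mu) = e^{-\mu} \mu^k / k!}. Evaluated in log space so that
#' large counts do not overflow \eqn{\mu^k} or \eqn{k!}.
#'
#' @param count non-negative integer spike count(s).
#' @param mu expected count(s), >= 0.
#' @return Probability, vectorized over `count` and `mu`.
#' @export
#' @examples
#' poisson_pmf(1, 1)            # exp(-1)
#' sum(poisson_pmf(0:200, 10))  # 1
poisson_pmf <- function(count, mu) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0) ||
      any(count != floor(count)))
    stop("count must be a non-negative integer")
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0))
    stop("mu must be non-negative")
  n <- max(length(count), length(mu))
  count <- rep_len(count, n); mu <- rep_len(mu, n)
  out <- numeric(n)
  z <- mu == 0
  out[z] <- as.numeric(count[z] == 0)
  nz <- !z
  out[nz] <- exp(count[nz] * log(mu[nz]) - mu[nz] - lgamma(count[nz] + 1))
  out
}

#' Spike train container
#'
#' A single trial's spike train: sorted spike times in ms on the half-open
#' interval `[0, duration)`. Simultaneous spikes are allowed (continuous
#' times make ties measure-zero; no deduplication is performed).
#'
#' @param times numeric vector of spike times, ms, non-decreasing, all in
#'   `[0, duration)`.
#' @param duration trial duration, ms (> 0).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times))) stop("non-finite spike times")
    if (is.unsorted(times)) stop("spike times must be non-decreasing")
    if (times[1L] < 0 || times[length(times)] >= duration)
      stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g ms\n",
              length(x$times), x$duration))
  invisible(x)
}

#' Homogeneous Poisson spike train
#'
#' Generates one realization of a homogeneous Poisson process at `rate`
#' spikes/s over `duration` ms: the spike count is Poisson(rate *
#' duration / 1000) and, conditional on the count, spike times are i.i.d.
#' uniform on `[0, duration)`, returned sorted.
#'
#' @param rate firing rate, spikes/s (>= 0).
#' @param duration trial duration, ms.
#' @return A [spike_train()].
#' @export
generate_homogeneous <- function(rate, duration = 1000) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 0) stop("rate must be non-negative")
  n <- stats::rpois(1L, rate * duration / 1000)
  spike_train(sort(stats::runif(n, 0, duration)), duration)
}

#' Inhomogeneous Poisson spike train by thinning
#'
#' Generates one realization of an inhomogeneous Poisson process with
#' intensity `rate_fn(t)` (spikes/s) by thinning: candidate events are drawn
#' from a homogeneous process at the ceiling rate `lambda_max` and each
#' candidate at time t is accepted with probability `rate_fn(t) /
#' lambda_max`. Exact for any bounded rate function; counts in any window
#' `[a, b)` are Poisson with mean `integral(rate)/1000`.
#'
#' @param rate_fn vectorized function of time (ms) returning spikes/s; must
#'   be non-negative and bounded by `lambda_max`.
#' @param duration trial duration, ms.
#' @param lambda_max finite upper bound on `rate_fn` over `[0, duration)`.
#' @return A [spike_train()].
#' @export
generate_inhomogeneous <- function(rate_fn, duration = 1000, lambda_max) {
  stopifnot(is.function(rate_fn), is.numeric(lambda_max),
            length(lambda_max) == 1L)
  if (!is.finite(lambda_max) || lambda_max < 0)
    stop("lambda_max must be finite and non-negative")
  if (lambda_max == 0) return(spike_train(numeric(0), duration))
  n <- stats::rpois(1L, lambda_max * duration / 1000)
  cand <- stats::runif(n, 0, duration)
  u <- stats::runif(n)
  r <- if (n) rate_fn(cand) else numeric(0)
  if (any(!is.finite(r)) || any(r < 0))
    stop("rate_fn returned negative or non-finite values")
  if (any(r > lambda_max * (1 + 1e-9)))
    stop("rate_fn exceeds lambda_max: thinning bound violated")
  spike_train(sort(cand[u * lambda_max < r]), duration)
}

#' Simulate a set of trials
#'
#' Repeats the generative recipe `n_trials` times: draw the trial's rate
#' (profile plus per-trial Gaussian offset, see [draw_trial_rate()]), then
#' generate spikes from it as an inhomogeneous Poisson process by thinning.
#'
#' RNG contract: `set.seed(seed)` initializes a root stream from which
#' `n_trials` per-trial seeds are taken as the first draws of
#' `sample.int(2^31 - 1)`; trial i is then generated under
#' `set.seed(trial_seed[i])`. Trial i is therefore reproducible
#' independently of `n_trials`, and regenerating with the same seed yields a
#' bit-identical trial set.
#'
#' @param profile a [rate_profile()].
#' @param noise a [noise_spec()].
#' @param n_trials number of trials (>= 2, so downstream variances exist).
#' @param seed integer root seed.
#' @return An object of class `trial_set`: fields `trials` (list of
#'   [spike_train()]), `duration`, `align_event` (ms; the profile's target
#'   onset, or 0 for constant profiles), `profile`, `noise`, `offsets` (the
#'   recorded per-trial rate offsets), `seed`, and `window` (current time
#'   support, `[0, duration)` until aligned).
#' @export
#' @examples
#' ts <- simulate_trialset(rate_profile("constant", baseline_rate = 20),
#'                         noise_spec("none"), n_trials = 10, seed = 1)
#' ts
simulate_trialset <- function(profile, noise = noise_spec("none"),
                              n_trials = 100, seed = 1) {
  stopifnot(inherits(profile, "rate_profile"), inherits(noise, "noise_spec"))
  if (!is.numeric(n_trials) || n_trials < 2)
    stop("n_trials must be >= 2 (across-trial variance undefined otherwise)")
  n_trials <- as.integer(n_trials)
  seed <- as.integer(seed)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  trials <- vector("list", n_trials)
  offsets <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(trial_seeds[i])
    tr <- draw_trial_rate(profile, noise)
    offsets[i] <- tr$offset
    trials[[i]] <- generate_inhomogeneous(tr$rate, profile$duration,
                                          tr$lambda_max)
  }
  align <- if (profile$kind == "task_epoch") profile$target_onset else 0
  new_trial_set(trials, profile = profile, noise = noise, offsets = offsets,
                seed = seed, align_event = align)
}

#' Assemble a trial set from spike trains
#'
#' Low-level constructor used by [simulate_trialset()] and the readers; most
#' users will not call it directly.
#'
#' @param trials list of [spike_train()] objects sharing one duration.
#' @param profile,noise generating [rate_profile()] / [noise_spec()], or
#'   `NULL` when unknown (e.g. external data).
#' @param offsets per-trial recorded rate offsets (length = number of
#'   trials).
#' @param seed integer seed of record (`NA` when unknown).
#' @param align_event event time in original trial coordinates, ms.
#' @param aligned whether spike times are already event-relative.
#' @param window time support `c(t0, t1)` of the spike times, ms.
#' @return A `trial_set` object.
#' @export
new_trial_set <- function(trials, profile = NULL, noise = NULL,
                          offsets = rep(0, length(trials)),
                          seed = NA_integer_, align_event = 0,
                          aligned = FALSE, window = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1L,
            all(vapply(trials, inherits, logical(1), "spike_train")))
  dur <- unique(vapply(trials, function(tr) tr$duration, numeric(1)))
  if (length(dur) != 1L) stop("all trials must share one duration")
  if (length(offsets) != length(trials))
    stop("offsets must have one entry per trial")
  if (is.null(window)) window <- c(0, dur)
  structure(
    list(trials = trials, duration = dur, align_event = as.numeric(align_event),
         profile = profile, noise = noise, offsets = as.numeric(offsets),
         seed = seed, aligned = isTRUE(aligned), window = as.numeric(window)),
    class = "trial_set")
}

#' Number of trials in a trial set
#' @param ts a `trial_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  length(ts$trials)
}

#' Per-trial spike counts in a window
#'
#' @param ts a `trial_set`.
#' @param window `c(a, b)` in the trial set's current time coordinates;
#'   counts spikes with `a <= t < b`. Defaults to the full support.
#' @return Integer vector, one count per trial.
#' @export
spike_counts <- function(ts, window = ts$window) {
  stopifnot(inherits(ts, "trial_set"), length(window) == 2L,
            window[2] > window[1])
  vapply(ts$trials,
         function(tr) sum(tr$times >= window[1] & tr$times < window[2]),
         numeric(1))
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %g ms, %s\n", n_trials(x), x$duration,
              if (x$aligned) sprintf("aligned (event at t = 0, window [%g, %g))",
                                     x$window[1], x$window[2])
              else "unaligned"))
  if (!is.null(x$profile)) print(x$profile)
  if (!is.null(x$noise)) print(x$noise)
  cat(sprintf("  mean count/trial: %.2f; seed: %s\n",
              mean(spike_counts(x)), format(x$seed)))
  invisible(x)
}
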
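#' Gaussian smoothing-kernel specification
#'
#' Parameters of the Gaussian kernel used to turn spike trains into spike
#' density functions (SDFs). The default SD of 30 ms is the standard choice
#' for reaching-task cortical data; the kernel is truncated at
#' `truncation * sigma` on each side and renormalized to exact unit area on
#' the evaluation grid.
#'
#' @param sigma Gaussian SD, ms (> 0). Default 30.
#' @param dt evaluation grid step, ms (> 0). Default 1.
#' @param truncation kernel support half-width in multiples of sigma
#'   (>= 3). Default 5.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma = 30, dt = 1, truncation = 5) {
  stopifnot(is.numeric(sigma), sigma > 0, is.numeric(dt), dt > 0,
            is.numeric(truncation), truncation >= 3)
  structure(list(sigma = as.numeric(sigma), dt = as.numeric(dt),
                 truncation = as.numeric(truncation)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> Gaussian sigma = %g ms, dt = %g ms, truncated at %g sigma\n",
              x$sigma, x$dt, x$truncation))
  invisible(x)
}

#' Discrete unit-area Gaussian kernel
#'
#' Evaluates the Gaussian density on the lag grid `seq(-J, J) * dt` with
#' `J = ceiling(truncation * sigma / dt)` and renormalizes so that
#' `dt * sum(weights) == 1` exactly (the truncated tail mass is folded back
#' multiplicatively). Weights are in 1/ms, symmetric and non-negative.
#'
#' @param spec a [kernel_spec()].
#' @return A list with `weights` (1/ms), `lags` (ms) and `spec`.
#' @export
gaussian_kernel <- function(spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  J <- ceiling(spec$truncation * spec$sigma / spec$dt)
  lags <- (-J:J) * spec$dt
  w <- stats::dnorm(lags, 0, spec$sigma)
  w <- w / (spec$dt * sum(w))
  list(weights = w, lags = lags, spec = spec)
}

#' Align trials to a per-trial event
#'
#' Re-expresses every spike time relative to an event (time 0 = event), e.g.
#' target presentation or movement onset, so that across-trial statistics
#' are computed peri-event. The common time support after the shift (the
#' intersection of the per-trial supports) is recorded as the trial set's
#' window.
#'
#' @param ts a `trial_set`.
#' @param event_times event time per trial, ms in `[0, duration]`; either a
#'   scalar (same event time in every trial) or a vector of length
#'   `n_trials(ts)`. Defaults to the trial set's `align_event`.
#' @return The aligned `trial_set`; `align_event` keeps the original event
#'   time(s) and `window` holds the common support `[-min(e), duration -
#'   max(e))`.
#' @export
align_trials <- function(ts, event_times = ts$align_event) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$aligned) stop("trial set is already aligned")
  n <- n_trials(ts)
  if (length(event_times) == 1L) event_times <- rep(event_times, n)
  if (length(event_times) != n)
    stop("event_times must be scalar or one per trial")
  bad <- which(!is.finite(event_times) | event_times < 0 |
                 event_times > ts$duration)
  if (length(bad))
    stop("missing or out-of-range event time for trial(s): ",
         paste(bad, collapse = ", "))
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- ts$trials[[i]]
    trials[[i]] <- structure(list(times = tr$times - event_times[i],
                                  duration = tr$duration),
                             class = "spike_train")
  }
  out <- ts
  out$trials <- trials
  out$aligned <- TRUE
  out$align_event <- if (length(unique(event_times)) == 1L) event_times[1]
                     else event_times
  out$window <- c(-min(event_times), ts$duration - max(event_times))
  out
}

# Row-wise linear convolution of a counts matrix with a centered kernel,
# via FFT. x: trials x nbins; w: odd-length kernel centered at (m+1)/2.
conv_rows <- function(x, w) {
  n <- ncol(x); m <- length(w); J <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L)
  W <- stats::fft(c(w, numeric(nf - m)))
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nf - n))))
  y <- Re(stats::mvfft(X * W, inverse = TRUE)) / nf
  t(y)[, (J + 1L):(J + n), drop = FALSE]
}

#' Spike density functions for every trial
#'
#' Replaces each spike by the unit-area Gaussian kernel and sums, yielding a
#' continuous firing-rate estimate per trial in spikes/s on a uniform time
#' grid. Spikes are binned to the nearest grid point (bin width `dt`) and
#' the binned counts convolved with the discrete kernel; the SDF is computed
#' on a window padded by `truncation * sigma` on each side and then cropped,
#' so spikes just outside the analysis window contribute and edge bias is
#' avoided.
#'
#' @param ts a `trial_set` (aligned or not; times are interpreted in the
#'   set's current coordinates).
#' @param spec a [kernel_spec()].
#' @param window analysis window `c(t0, t1)`, ms, within the trial set's
#'   support; defaults to the full support.
#' @return An object of class `sdf_matrix`: `values` (trials x time matrix,
#'   spikes/s), `time_grid` (ms), `kernel` (the [kernel_spec()]), and
#'   `n_trials`.
#' @export
compute_sdf <- function(ts, spec = kernel_spec(), window = ts$window) {
  stopifnot(inherits(ts, "trial_set"), inherits(spec, "kernel_spec"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[2] <= window[1])
    stop("empty or invalid analysis window")
  if (window[1] < ts$window[1] - 1e-9 || window[2] > ts$window[2] + 1e-9)
    stop("analysis window outside the data support [",
         ts$window[1], ", ", ts$window[2], ")")
  dt <- spec$dt
  pad <- spec$truncation * spec$sigma
  nb_win <- round((window[2] - window[1]) / dt)
  if (nb_win < 1L) stop("empty analysis window at this dt")
  npad <- ceiling(pad / dt)
  t0p <- window[1] - npad * dt
  nb <- nb_win + 2L * npad
  ntr <- n_trials(ts)
  counts <- matrix(0, ntr, nb)
  for (i in seq_len(ntr)) {
    idx <- round((ts$trials[[i]]$times - t0p) / dt) + 1L
    idx <- idx[idx >= 1L & idx <= nb]
    if (length(idx)) counts[i, ] <- tabulate(idx, nbins = nb)
  }
  kern <- gaussian_kernel(spec)
  # FFT round-off can leave values a few ulp below zero; rates are >= 0
  values <- pmax(1000 * conv_rows(counts, kern$weights), 0)
  keep <- (npad + 1L):(npad + nb_win)
  structure(list(values = values[, keep, drop = FALSE],
                 time_grid = t0p + (keep - 1L) * dt,
                 kernel = spec, n_trials = ntr),
            class = "sdf_matrix")
}

#' @export
print.sdf_matrix <- function(x, ...) {
  cat(sprintf("<sdf_matrix> %d trials x %d time bins ([%g, %g] ms, dt = %g), sigma = %g ms\n",
              x$n_trials, length(x$time_grid), x$time_grid[1],
              x$time_grid[length(x$time_grid)], x$kernel$dt, x$kernel$sigma))
  cat(sprintf("  grand mean rate: %.2f spikes/s\n", mean(x$values)))
  invisible(x)
}

#' Trial-averaged SDF and across-trial variance
#'
#' Pointwise mean firing rate (the population SDF, i.e. the per-trial SDFs
#' averaged over trials) and the unbiased (n - 1) across-trial variance at
#' each time point.
#'
#' @param m an `sdf_matrix` with at least 2 trials.
#' @return A data frame with columns `time_ms`, `mean` (spikes/s) and `var`
#'   ((spikes/s)^2).
#' @export
mean_sdf <- function(m) {
  stopifnot(inherits(m, "sdf_matrix"))
  if (m$n_trials < 2) stop("need >= 2 trials for an across-trial variance")
  mu <- colMeans(m$values)
  v <- colSums(sweep(m$values, 2, mu)^2) / (m$n_trials - 1)
  data.frame(time_ms = m$time_grid, mean = mu, var = v)
}
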
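#' Regularizing constants of the normalized-variance statistic
#'
#' The time-resolved normalized variance is
#' \deqn{NV(t) = \frac{k\,\varepsilon + Var(SDF(t))}{k\,\varepsilon' +
#'   Mean(SDF(t))}}
#' where the small constants keep the ratio defined when mean and variance
#' vanish (all-empty trials give NV = k\eqn{\varepsilon}/k\eqn{\varepsilon'}
#' = 1). Defaults: k = 0.1, \eqn{\varepsilon} = \eqn{\varepsilon'} = 0.01.
#'
#' @param k dimensionless, > 0.
#' @param eps numerator regularizer, > 0.
#' @param eps_prime denominator regularizer, > 0.
#' @return An object of class `nv_constants`.
#' @export
nv_constants <- function(k = 0.1, eps = 0.01, eps_prime = 0.01) {
  stopifnot(is.numeric(k), k > 0, is.numeric(eps), eps > 0,
            is.numeric(eps_prime), eps_prime > 0)
  structure(list(k = as.numeric(k), eps = as.numeric(eps),
                 eps_prime = as.numeric(eps_prime)),
            class = "nv_constants")
}

#' Kernel variance-correction factor
#'
#' For a homogeneous Poisson process smoothed with a unit-area kernel, the
#' across-trial variance of the SDF is not equal to its mean: by Campbell's
#' theorem it is a kernel-dependent multiple of it,
#' \eqn{Var(SDF(t)) = c \cdot Mean(SDF(t))} with
#' \eqn{c = 1000 \, dt \sum_j k_j^2} (in spikes/s; for a Gaussian kernel
#' \eqn{dt \sum k^2 \to \int K^2 = 1/(2\sigma\sqrt{\pi})}). Dividing the
#' variance by `c` therefore calibrates the variance-to-mean ratio so a pure
#' Poisson process has expectation 1 — the "NV is unity" reference point.
#' With a delta kernel (`sigma -> dt`) `c` reduces to the 1-ms count-bin
#' Fano scale.
#'
#' @param spec a [kernel_spec()].
#' @return The correction `c` (spikes/s scale), a positive scalar.
#' @export
kernel_correction <- function(spec = kernel_spec()) {
  k <- gaussian_kernel(spec)
  1000 * spec$dt * sum(k$weights^2)
}

new_nv_series <- function(time_grid, nv, mode, constants, n_trials,
                          window = NA_real_) {
  structure(list(time_grid = as.numeric(time_grid), nv = as.numeric(nv),
                 mode = mode, constants = constants,
                 n_trials = as.integer(n_trials),
                 window = as.numeric(window)),
            class = "nv_series")
}

#' Time-resolved normalized variance of an SDF matrix
#'
#' Computes NV(t), the regularized variance-to-mean ratio of the spike
#' density function across trials, in one of two modes:
#' \describe{
#'   \item{`raw_eq1`}{the ratio exactly as defined,
#'     `(k*eps + Var) / (k*eps_prime + Mean)`. For kernel-smoothed Poisson
#'     input its expectation is the kernel constant [kernel_correction()],
#'     not 1.}
#'   \item{`calibrated`}{(default) the across-trial variance is first
#'     divided by [kernel_correction()] so that a pure Poisson process
#'     yields NV with expectation 1 and rate-noise contamination pushes it
#'     above 1; the regularizers are then applied identically.}
#' }
#'
#' @param m an `sdf_matrix` (>= 2 trials).
#' @param constants an [nv_constants()].
#' @param mode `"calibrated"` or `"raw_eq1"`.
#' @return An object of class `nv_series` with fields `time_grid`, `nv`,
#'   `mode`, `constants`, `n_trials`.
#' @seealso [count_fano()] for the count-window oracle.
#' @export
nv_series <- function(m, constants = nv_constants(),
                      mode = c("calibrated", "raw_eq1")) {
  stopifnot(inherits(m, "sdf_matrix"), inherits(constants, "nv_constants"))
  mode <- match.arg(mode)
  if (m$n_trials < 2) stop("need >= 2 trials to compute NV")
  ms <- mean_sdf(m)
  v <- ms$var
  if (mode == "calibrated") v <- v / kernel_correction(m$kernel)
  nv <- (constants$k * constants$eps + v) /
    (constants$k * constants$eps_prime + ms$mean)
  new_nv_series(ms$time_ms, nv, mode, constants, m$n_trials)
}

#' @export
print.nv_series <- function(x, ...) {
  cat(sprintf("<nv_series> mode = %s, %d time bins, %d trials%s\n",
              x$mode, length(x$time_grid), x$n_trials,
              if (!is.na(x$window[1])) sprintf(", window = %g ms", x$window)
              else ""))
  cat(sprintf("  time-mean NV: %.3f (k = %g, eps = %g, eps' = %g)\n",
              mean(x$nv), x$constants$k, x$constants$eps,
              x$constants$eps_prime))
  invisible(x)
}

#' Sliding-window count Fano factor
#'
#' The count-based analogue of NV and its independent oracle: spike counts
#' per trial in a sliding window, then at each window position the
#' regularized variance-to-mean ratio across trials. For a homogeneous
#' Poisson process its expectation is 1 at every t with no kernel
#' correction; under additive per-trial rate noise of SD sigma it is
#' `1 + sigma^2 * (w/1000) / lambda`.
#'
#' @param ts a `trial_set` (aligned or not).
#' @param window window width w, ms (>= 1), must fit inside the data span.
#' @param step window step, ms; default `window / 2`.
#' @param constants an [nv_constants()].
#' @return An `nv_series` with `mode = "count_fano"`; `time_grid` holds the
#'   window centers and `window` the width.
#' @export
count_fano <- function(ts, window = 100, step = window / 2,
                       constants = nv_constants()) {
  stopifnot(inherits(ts, "trial_set"), inherits(constants, "nv_constants"))
  if (n_trials(ts) < 2) stop("need >= 2 trials")
  span <- ts$window
  if (!is.numeric(window) || window < 1) stop("window must be >= 1 ms")
  if (window > span[2] - span[1])
    stop("window larger than the data span")
  starts <- seq(span[1], span[2] - window, by = step)
  n <- n_trials(ts)
  counts <- matrix(0, n, length(starts))
  for (i in seq_len(n)) {
    tt <- ts$trials[[i]]$times
    # counts of spikes in [start, start + window)
    counts[i, ] <- findInterval(starts + window, tt, left.open = TRUE) -
      findInterval(starts, tt, left.open = TRUE)
  }
  mu <- colMeans(counts)
  v <- colSums(sweep(counts, 2, mu)^2) / (n - 1)
  fano <- (constants$k * constants$eps + v) /
    (constants$k * constants$eps_prime + mu)
  new_nv_series(starts + window / 2, fano, "count_fano", constants, n,
                window = window)
}

#' NV distribution by firing-rate level
#'
#' Relates variability to activity: each time bin is assigned to a level by
#' its normalized mean rate (fraction of the maximum mean rate), by default
#' the levels 0.8-1.0 of max, 0.5-0.8, and below 0.5, and the NV samples of
#' each level are summarized. Under additive per-trial rate noise the
#' expected NV decreases with the level rate (the inverse NV-rate
#' relation).
#'
#' @param nv an `nv_series`.
#' @param mean_rate mean firing rate at the same time points as `nv`
#'   (spikes/s); e.g. the `mean` column of [mean_sdf()]. `max(mean_rate)`
#'   must be > 0.
#' @param edges level edges as decreasing fractions of the maximum rate;
#'   default `c(1, 0.8, 0.5, 0)`. Level j covers `[edges[j+1], edges[j])`,
#'   the top level includes 1.
#' @return An object of class `rate_level_bins`: a data frame with one row
#'   per level, columns `level`, `lo`, `hi` (fractions of max), `nv_mean`,
#'   `nv_sd`, `n` (time bins in the level; empty levels are reported with
#'   `n = 0`, not dropped). Rows are ordered from the highest rate level
#'   down.
#' @export
rate_level_nv <- function(nv, mean_rate, edges = c(1, 0.8, 0.5, 0)) {
  stopifnot(inherits(nv, "nv_series"), is.numeric(mean_rate))
  if (length(mean_rate) != length(nv$time_grid))
    stop("mean_rate must share the NV time grid")
  if (any(!is.finite(mean_rate)) || max(mean_rate) <= 0)
    stop("max(mean_rate) must be positive")
  edges <- sort(unique(as.numeric(edges)), decreasing = TRUE)
  if (length(edges) < 2 || edges[1] != 1 || edges[length(edges)] != 0)
    stop("edges must run from 1 down to 0")
  frac <- mean_rate / max(mean_rate)
  brk <- sort(edges)                      # increasing, 0 ... 1
  lev_low_first <- findInterval(frac, brk, rightmost.closed = TRUE)
  nlev <- length(edges) - 1L
  lev <- nlev + 1L - lev_low_first        # 1 = top level
  rows <- lapply(seq_len(nlev), function(j) {
    sel <- lev == j
    data.frame(level = sprintf("%g-%g", edges[j + 1L], edges[j]),
               lo = edges[j + 1L], hi = edges[j],
               nv_mean = if (any(sel)) mean(nv$nv[sel]) else NA_real_,
               nv_sd = if (sum(sel) > 1) stats::sd(nv$nv[sel]) else NA_real_,
               n = sum(sel))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_level_bins", "data.frame")
  out
}

#' Pool NV series across simulated units
#'
#' Pointwise mean and standard error of several NV series sharing one time
#' grid, as when variability is averaged across neurons and movement
#' directions.
#'
#' @param series list of `nv_series` objects with identical time grids and
#'   mode.
#' @return A data frame of class `pooled_nv` with columns `time_ms`,
#'   `nv_mean`, `nv_se` (`NA` for a single series) and attribute
#'   `n_series`.
#' @export
pool_nv <- function(series) {
  stopifnot(is.list(series), length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "nv_series")))
  grid <- series[[1L]]$time_grid
  for (s in series[-1L])
    if (length(s$time_grid) != length(grid) ||
        any(abs(s$time_grid - grid) > 1e-9))
      stop("all NV series must share the same time grid")
  mode <- unique(vapply(series, function(s) s$mode, character(1)))
  if (length(mode) != 1L) stop("all NV series must share one mode")
  m <- do.call(rbind, lapply(series, function(s) s$nv))
  ns <- length(series)
  se <- if (ns > 1L) apply(m, 2L, stats::sd) / sqrt(ns)
        else rep(NA_real_, length(grid))
  out <- data.frame(time_ms = grid, nv_mean = colMeans(m), nv_se = se)
  attr(out, "n_series") <- ns
  attr(out, "mode") <- mode
  class(out) <- c("pooled_nv", "data.frame")
  out
}
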
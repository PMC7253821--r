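#' Deterministic trial rate profile
#'
#' Constructs the deterministic instantaneous firing-rate signal
#' \eqn{\lambda(t)} underlying a simulated trial. Two shapes are supported:
#' a constant rate over the whole trial, and a task-epoch profile that sits
#' at a baseline rate, then ramps linearly to a peak rate over `rise_time`
#' milliseconds starting at `target_onset` (the stimulus/target presentation
#' the trials are later aligned to).
#'
#' @param kind profile shape, `"constant"` or `"task_epoch"`.
#' @param duration trial duration in ms (> 0).
#' @param baseline_rate baseline firing rate, spikes/s (>= 0).
#' @param peak_rate post-onset plateau rate, spikes/s (`task_epoch` only).
#' @param target_onset onset of the rate ramp, ms into the trial
#'   (`task_epoch` only).
#' @param rise_time duration of the linear ramp from baseline to peak, ms
#'   (`task_epoch` only); `target_onset + rise_time` must not exceed
#'   `duration`.
#'
#' @return An object of class `rate_profile`.
#' @seealso [evaluate_rate()], [noise_spec()], [simulate_trialset()]
#' @export
#' @examples
#' rate_profile("constant", baseline_rate = 20)
#' rate_profile("task_epoch", baseline_rate = 5, peak_rate = 45,
#'              target_onset = 400, rise_time = 200)
rate_profile <- function(kind = c("constant", "task_epoch"),
                         duration = 1000,
                         baseline_rate = 20,
                         peak_rate = NULL,
                         target_onset = NULL,
                         rise_time = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(baseline_rate), length(baseline_rate) == 1L,
            baseline_rate >= 0)
  if (kind == "task_epoch") {
    if (is.null(peak_rate) || is.null(target_onset) || is.null(rise_time))
      stop("task_epoch profiles require peak_rate, target_onset and rise_time")
    stopifnot(is.numeric(peak_rate), peak_rate >= 0,
              is.numeric(target_onset), target_onset >= 0,
              target_onset <= duration,
              is.numeric(rise_time), rise_time >= 0)
    if (target_onset + rise_time > duration)
      stop("target_onset + rise_time exceeds trial duration")
  } else {
    peak_rate <- NULL; target_onset <- NULL; rise_time <- NULL
  }
  structure(
    list(kind = kind, duration = as.numeric(duration),
         baseline_rate = as.numeric(baseline_rate),
         peak_rate = if (!is.null(peak_rate)) as.numeric(peak_rate),
         target_onset = if (!is.null(target_onset)) as.numeric(target_onset),
         rise_time = if (!is.null(rise_time)) as.numeric(rise_time)),
    class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("<rate_profile> constant %g spikes/s over %g ms\n",
                x$baseline_rate, x$duration))
  } else {
    cat(sprintf(
      "<rate_profile> task_epoch %g -> %g spikes/s, onset %g ms, rise %g ms, duration %g ms\n",
      x$baseline_rate, x$peak_rate, x$target_onset, x$rise_time, x$duration))
  }
  invisible(x)
}

#' Maximum value of a rate profile
#'
#' @param profile a [rate_profile()].
#' @return Upper bound of \eqn{\lambda(t)} in spikes/s.
#' @export
max_rate <- function(profile) {
  stopifnot(inherits(profile, "rate_profile"))
  if (profile$kind == "constant") profile$baseline_rate
  else max(profile$baseline_rate, profile$peak_rate)
}

#' Evaluate the deterministic rate profile
#'
#' Returns \eqn{\lambda(t)} in spikes/s. Constant profiles return the
#' baseline everywhere; task-epoch profiles return the baseline before
#' `target_onset`, interpolate linearly over the ramp, and return the peak
#' rate afterwards. The result is piecewise-continuous and bounded by
#' `max_rate(profile)`.
#'
#' @param profile a [rate_profile()].
#' @param t time(s) in ms; every value must lie in `[0, duration)`.
#' @return Numeric vector of rates, spikes/s, same length as `t`.
#' @export
#' @examples
#' p <- rate_profile("task_epoch", baseline_rate = 5, peak_rate = 45,
#'                   target_onset = 400, rise_time = 100)
#' evaluate_rate(p, c(399, 450, 600))  # 5, 25, 45
evaluate_rate <- function(profile, t) {
  stopifnot(inherits(profile, "rate_profile"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0) || any(t >= profile$duration))
    stop("t outside [0, duration): rate profile undefined there")
  if (profile$kind == "constant")
    return(rep.int(profile$baseline_rate, length(t)))
  b <- profile$baseline_rate; p <- profile$peak_rate
  on <- profile$target_onset; rise <- profile$rise_time
  frac <- if (rise > 0) pmin(1, pmax(0, (t - on) / rise)) else as.numeric(t >= on)
  b + (p - b) * frac
}

#' Per-trial Gaussian rate-noise specification
#'
#' Describes how the deterministic rate profile is perturbed from trial to
#' trial. With `kind = "additive_offset"` each trial receives a single
#' Gaussian offset \eqn{\eta_i \sim N(0, \sigma^2)} (spikes/s), constant over
#' the trial, added to the profile; this is the doubly stochastic ("noisy
#' Poisson") ingredient. With `kind = "none"` the trial rate equals the
#' profile exactly.
#'
#' @param kind `"none"` or `"additive_offset"`.
#' @param sigma standard deviation of the per-trial rate offset, spikes/s
#'   (>= 0; ignored when `kind = "none"`).
#' @param clip_at_zero if `TRUE` (default) the realized trial rate is clipped
#'   at zero (rates are intensities and cannot be negative). Clipping biases
#'   the realized mean rate upward when `sigma` is comparable to the rate;
#'   see the methods vignette.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "additive_offset"), sigma = 0,
                       clip_at_zero = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.logical(clip_at_zero), length(clip_at_zero) == 1L)
  if (kind == "none") sigma <- 0
  structure(list(kind = kind, sigma = as.numeric(sigma),
                 clip_at_zero = clip_at_zero),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s, sigma = %g spikes/s, clip_at_zero = %s\n",
              x$kind, x$sigma, x$clip_at_zero))
  invisible(x)
}

#' Draw one trial's realized rate function
#'
#' Draws the per-trial Gaussian offset \eqn{\eta_i} from the current RNG
#' stream and returns the realized trial rate
#' \eqn{\lambda_i(t) = \max(0, \lambda(t) + \eta_i)} (clipping only if
#' requested) together with the recorded offset and an upper bound usable
#' for thinning.
#'
#' @param profile a [rate_profile()].
#' @param noise a [noise_spec()].
#' @return A list with elements `rate` (vectorized function of t, spikes/s),
#'   `offset` (the drawn \eqn{\eta_i}, 0 when `kind = "none"`) and
#'   `lambda_max` (bound on the realized rate).
#' @export
draw_trial_rate <- function(profile, noise) {
  stopifnot(inherits(profile, "rate_profile"), inherits(noise, "noise_spec"))
  offset <- if (noise$kind == "none") 0 else stats::rnorm(1L, 0, noise$sigma)
  clip <- isTRUE(noise$clip_at_zero)
  rate <- function(t) {
    r <- evaluate_rate(profile, t) + offset
    if (clip) pmax(0, r) else r
  }
  lmax <- max_rate(profile) + offset
  if (clip) lmax <- max(0, lmax)
  list(rate = rate, offset = offset, lambda_max = lmax)
}
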
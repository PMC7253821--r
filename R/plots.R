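#' Raster plot of a trial set
#'
#' One row of tick marks per trial; a vertical line marks the alignment
#' event. Plots the first `max_trials` trials of the set.
#'
#' @param ts a `trial_set`.
#' @param max_trials number of trials to draw, default 50.
#' @param ... passed to [graphics::plot()].
#' @return `ts`, invisibly.
#' @export
plot_raster <- function(ts, max_trials = 50, ...) {
  stopifnot(inherits(ts, "trial_set"))
  m <- min(max_trials, n_trials(ts))
  graphics::plot(NA, xlim = ts$window, ylim = c(0.5, m + 0.5),
                 xlab = if (ts$aligned) "time from event (ms)" else "time (ms)",
                 ylab = "trial", ...)
  for (i in seq_len(m)) {
    tt <- ts$trials[[i]]$times
    if (length(tt))
      graphics::segments(tt, i - 0.4, tt, i + 0.4)
  }
  ev <- if (ts$aligned) 0 else ts$align_event
  graphics::abline(v = ev, col = "red", lty = 2)
  invisible(ts)
}

#' @export
plot.nv_series <- function(x, ...) {
  graphics::plot(x$time_grid, x$nv, type = "l",
                 xlab = "time (ms)", ylab = sprintf("NV (%s)", x$mode), ...)
  graphics::abline(h = 1, col = "grey", lty = 2)
  invisible(x)
}

#' @export
plot.sdf_matrix <- function(x, ...) {
  ms <- mean_sdf(x)
  graphics::plot(ms$time_ms, ms$mean, type = "l",
                 xlab = "time (ms)", ylab = "mean firing rate (spikes/s)", ...)
  invisible(x)
}
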
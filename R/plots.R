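#' Plot signal traces
#'
#' Stacked base-graphics view of the channels against time.
#'
#' @param x A trace.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.piezo_trace <- function(x, ...) {
  t <- trace_times(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$channels))
    graphics::plot(t, x$channels[[nm]], type = "l", xlab = "time [s]",
                   ylab = nm, ...)
  invisible(x)
}

#' @rdname plot.piezo_trace
#' @export
plot.accel_trace <- function(x, ...) {
  t <- trace_times(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$channels))
    graphics::plot(t, x$channels[[nm]], type = "l", xlab = "time [s]",
                   ylab = paste(nm, "[g]"), ...)
  invisible(x)
}
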
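#' Multichannel signal traces
#'
#' `piezo_trace()` holds the three piezoelectric channels (PZ1 left temple,
#' PZ2 right temple, PZ3 cheek) sampled at a nominal 1000 Hz; `accel_trace()`
#' holds the x/z acceleration axes (in g) sampled at a nominal 200 Hz. Both
#' are plain lists with class attributes so that downstream operations can
#' dispatch without assuming a global sampling rate.
#'
#' @param pz1,pz2,pz3 Numeric amplitude series (arbitrary voltage-proportional
#'   units); must have identical length >= 1.
#' @param sample_rate Samples per second; must be > 0.
#' @param t0 Start time in seconds.
#' @return An object of class `"piezo_trace"` or `"accel_trace"`.
#' @examples
#' tr <- piezo_trace(pz1 = rnorm(1000), pz2 = rnorm(1000), pz3 = rnorm(1000))
#' n_samples(tr)
#' duration(tr)
#' @export
piezo_trace <- function(pz1, pz2, pz3, sample_rate = 1000, t0 = 0) {
  pz1 <- as.numeric(pz1); pz2 <- as.numeric(pz2); pz3 <- as.numeric(pz3)
  if (length(pz1) < 1L)
    stop("piezo_trace: channels must contain at least one sample", call. = FALSE)
  if (length(pz1) != length(pz2) || length(pz1) != length(pz3))
    stop("piezo_trace: all three channels must have identical length", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("piezo_trace: sample_rate must be > 0", call. = FALSE)
  structure(
    list(channels = list(pz1 = pz1, pz2 = pz2, pz3 = pz3),
         sample_rate = sample_rate, t0 = t0),
    class = "piezo_trace"
  )
}

#' @param ax,az Numeric acceleration series in g; identical length >= 1.
#' @rdname piezo_trace
#' @export
accel_trace <- function(ax, az, sample_rate = 200, t0 = 0) {
  ax <- as.numeric(ax); az <- as.numeric(az)
  if (length(ax) < 1L)
    stop("accel_trace: axes must contain at least one sample", call. = FALSE)
  if (length(ax) != length(az))
    stop("accel_trace: ax and az must have identical length", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("accel_trace: sample_rate must be > 0", call. = FALSE)
  structure(
    list(channels = list(ax = ax, az = az),
         sample_rate = sample_rate, t0 = t0),
    class = "accel_trace"
  )
}

#' @rdname piezo_trace
#' @param x A trace object.
#' @export
n_samples <- function(x) length(x$channels[[1L]])

#' @rdname piezo_trace
#' @export
duration <- function(x) n_samples(x) / x$sample_rate

#' @export
print.piezo_trace <- function(x, ...) {
  cat(sprintf("<piezo_trace> 3 channels (pz1, pz2, pz3), %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              n_samples(x), x$sample_rate, duration(x), x$t0))
  invisible(x)
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> 2 axes (ax, az) [g], %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              n_samples(x), x$sample_rate, duration(x), x$t0))
  invisible(x)
}

trace_times <- function(x) x$t0 + (seq_len(n_samples(x)) - 1L) / x$sample_rate

#' Extract a time window from a trace
#'
#' Returns the samples with `from <= t < to` as a new trace of the same class.
#'
#' @param x A `piezo_trace` or `accel_trace`.
#' @param from,to Window bounds in seconds (same clock as `t0`).
#' @return A trace of the same class.
#' @export
trace_window <- function(x, from, to) {
  t <- trace_times(x)
  keep <- t >= from - 1e-9 & t < to - 1e-9
  if (!any(keep))
    stop("trace_window: window contains no samples", call. = FALSE)
  ch <- lapply(x$channels, function(v) v[keep])
  if (inherits(x, "piezo_trace"))
    piezo_trace(ch$pz1, ch$pz2, ch$pz3, x$sample_rate, t0 = t[which(keep)[1L]])
  else
    accel_trace(ch$ax, ch$az, x$sample_rate, t0 = t[which(keep)[1L]])
}

#' Read and write trace CSV files
#'
#' Traces are stored as plain CSV with a header row `time,pz1,pz2,pz3` (piezo)
#' or `time,ax,az` (accelerometer); time in seconds, strictly increasing and
#' uniformly spaced. The sampling rate is inferred from the median time step
#' and validated against the declared kind's nominal rate (1000 or 200 Hz)
#' within 1%; timestamp jitter above 1% of the nominal step is rejected.
#'
#' @param path File path.
#' @param kind `"piezo"` or `"accel"`.
#' @return `read_trace()` returns a `piezo_trace` or `accel_trace`;
#'   `write_trace()` returns `path` invisibly. Round-trips are lossless to
#'   9 significant digits.
#' @export
read_trace <- function(path, kind = c("piezo", "accel")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  want <- if (kind == "piezo") c("time", "pz1", "pz2", "pz3") else c("time", "ax", "az")
  if (!identical(names(df), want))
    stop(sprintf("read_trace: malformed header; expected '%s', got '%s'",
                 paste(want, collapse = ","), paste(names(df), collapse = ",")),
         call. = FALSE)
  t <- df$time
  if (nrow(df) >= 2L) {
    dt <- diff(t)
    step <- stats::median(dt)
    if (any(dt <= 0) || any(abs(dt - step) > 0.01 * step))
      stop("read_trace: timestamps must be strictly increasing and uniformly spaced (<1% jitter)",
           call. = FALSE)
    rate <- 1 / step
  } else {
    rate <- if (kind == "piezo") 1000 else 200
  }
  nominal <- if (kind == "piezo") 1000 else 200
  if (abs(rate - nominal) > 0.01 * nominal)
    stop(sprintf("read_trace: inferred rate %.1f Hz differs from nominal %d Hz by more than 1%%",
                 rate, nominal), call. = FALSE)
  if (kind == "piezo")
    piezo_trace(df$pz1, df$pz2, df$pz3, sample_rate = rate, t0 = t[1L])
  else
    accel_trace(df$ax, df$az, sample_rate = rate, t0 = t[1L])
}

#' @param x A trace to write.
#' @rdname read_trace
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "piezo_trace") || inherits(x, "accel_trace"))
  df <- data.frame(time = trace_times(x))
  for (nm in names(x$channels)) df[[nm]] <- x$channels[[nm]]
  # 9 significant digits keeps round-trips lossless for realistic amplitudes
  for (nm in names(df)) df[[nm]] <- formatC(df[[nm]], digits = 9, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The five-state command vocabulary
#'
#' Commands are represented as character strings from a fixed vocabulary:
#' `TURN_LEFT`, `TURN_RIGHT`, `FORWARD`, `BACKWARD` plus the default
#' no-action state `IDLE`.
#'
#' @return `command_levels()` returns the five states in canonical order;
#'   `as_command()` validates and normalises a character vector against them.
#' @param x Character vector of command names.
#' @export
command_levels <- function() c("TURN_LEFT", "TURN_RIGHT", "FORWARD", "BACKWARD", "IDLE")

#' @rdname command_levels
#' @export
as_command <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), command_levels())
  if (length(bad))
    stop("as_command: unknown command(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}
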
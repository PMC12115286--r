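#' IIR preprocessing filters
#'
#' Both interfaces preprocess their raw streams with causal, single-pass IIR
#' filters before feature extraction (a real-time system cannot use zero-phase
#' two-pass filtering). The piezo chain removes baseline drift, high-frequency
#' noise and mains interference: a 3 Hz high-pass, an 80 Hz low-pass and a
#' 50 Hz notch, applied in that order to each channel. The accelerometer chain
#' is a 0.1-20 Hz band-pass.
#'
#' High/low/band-pass stages are 4th-order Butterworth designs
#' ([signal::butter()]); the notch is a 2nd-order constrained biquad with
#' quality factor Q = 30 (bandwidth f0/Q ~ 1.7 Hz), which `signal` does not
#' provide and is designed here directly.
#'
#' @name filters
NULL

#' Filter design specification
#'
#' @param kind One of `"highpass"`, `"lowpass"`, `"notch"`, `"bandpass"`.
#' @param cutoffs Cutoff (or centre) frequency in Hz; two values for bandpass.
#' @param order Filter order (Butterworth stages).
#' @param notch_q Quality factor, notch only.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "notch", "bandpass"),
                        cutoffs, order = 4L, notch_q = 30) {
  kind <- match.arg(kind)
  cutoffs <- as.numeric(cutoffs)
  n_expect <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs) != n_expect || any(cutoffs <= 0))
    stop("filter_spec: need ", n_expect, " positive cutoff(s) for ", kind, call. = FALSE)
  if (kind == "bandpass" && cutoffs[1] >= cutoffs[2])
    stop("filter_spec: bandpass cutoffs must be increasing", call. = FALSE)
  structure(list(kind = kind, cutoffs = cutoffs, order = as.integer(order),
                 notch_q = notch_q),
            class = "filter_spec")
}

#' Realise a filter_spec as transfer-function coefficients
#'
#' @param spec A [filter_spec()].
#' @param sample_rate Sampling rate in Hz; all cutoffs must lie strictly below
#'   the Nyquist frequency.
#' @return A list with `b` (numerator) and `a` (denominator) coefficients.
#' @export
design_filter <- function(spec, sample_rate) {
  nyq <- sample_rate / 2
  if (any(spec$cutoffs >= nyq))
    stop(sprintf("design_filter: cutoff(s) %s Hz not below Nyquist (%g Hz)",
                 paste(spec$cutoffs, collapse = "/"), nyq), call. = FALSE)
  if (spec$kind == "notch") {
    # constrained biquad: zeros on the unit circle at +/- w0, poles pulled in
    # by the bandwidth f0/Q (RBJ audio-EQ parameterisation)
    w0 <- 2 * pi * spec$cutoffs / sample_rate
    alpha <- sin(w0) / (2 * spec$notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    return(list(b = b, a = a))
  }
  W <- spec$cutoffs / nyq
  type <- switch(spec$kind, highpass = "high", lowpass = "low", bandpass = "pass")
  fl <- signal::butter(spec$order, W, type = type)
  list(b = as.numeric(fl$b), a = as.numeric(fl$a))
}

#' Frequency response magnitude of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| directly from the transfer-function
#' polynomials; used to verify pass-band fidelity and stop-band attenuation.
#'
#' @param coefs A list with `b`, `a` as from [design_filter()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @return Numeric vector of gains (linear magnitude).
#' @export
filter_gain <- function(coefs, freq_hz, sample_rate) {
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / sample_rate)
    zp <- z^(seq_along(coefs$b) - 1L)
    za <- z^(seq_along(coefs$a) - 1L)
    Mod(sum(coefs$b * zp) / sum(coefs$a * za))
  }, numeric(1))
}

apply_filter <- function(coefs, x) {
  as.numeric(signal::filter(signal::Arma(b = coefs$b, a = coefs$a), x))
}

#' Piezo channel filter chain
#'
#' Passes every channel, in order, through the 3 Hz high-pass, 80 Hz low-pass
#' and 50 Hz notch. Causal, deterministic, length-preserving.
#'
#' @param trace A [piezo_trace()] with `sample_rate >= 200` (the 80 Hz cutoff
#'   must lie below Nyquist).
#' @return A filtered `piezo_trace` of identical length.
#' @export
filter_piezo <- function(trace) {
  stopifnot(inherits(trace, "piezo_trace"))
  fs <- trace$sample_rate
  if (fs < 200)
    stop("filter_piezo: sample_rate must be >= 200 Hz for the 80 Hz cutoff", call. = FALSE)
  chain <- list(design_filter(filter_spec("highpass", 3), fs),
                design_filter(filter_spec("lowpass", 80), fs),
                design_filter(filter_spec("notch", 50), fs))
  ch <- lapply(trace$channels, function(v) {
    for (co in chain) v <- apply_filter(co, v)
    v
  })
  piezo_trace(ch$pz1, ch$pz2, ch$pz3, fs, t0 = trace$t0)
}

#' Accelerometer band-pass filter
#'
#' Applies the 0.1-20 Hz band-pass to both axes. Note that this removes the
#' quasi-static (sub-0.1 Hz) component of a sustained head tilt, which the
#' amplitude-threshold classifier relies on; the command pipeline therefore
#' leaves it off by default (`accel_filter` flag in [pipeline_config()]).
#'
#' @param trace An [accel_trace()] with `sample_rate >= 40` Hz.
#' @return A filtered `accel_trace` of identical length.
#' @export
filter_accel <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- trace$sample_rate
  if (fs < 40)
    stop("filter_accel: sample_rate must be >= 40 Hz for the 20 Hz cutoff", call. = FALSE)
  co <- design_filter(filter_spec("bandpass", c(0.1, 20)), fs)
  accel_trace(apply_filter(co, trace$channels$ax),
              apply_filter(co, trace$channels$az),
              fs, t0 = trace$t0)
}
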
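#' Command pipeline configuration
#'
#' Settings of the streaming loop that turns a raw trace into a command
#' stream: the command period (one command every `command_period` seconds),
#' the analysis window (the final `window` seconds before each decision
#' instant), filter flags and the head-interface window statistic.
#'
#' `accel_filter` defaults to `FALSE`: the 0.1-20 Hz band-pass removes the
#' quasi-static tilt plateau that the threshold classifier measures, so the
#' filtered and unfiltered behaviours are both available but the unfiltered
#' path is the working default.
#'
#' @param modality `"face"` or `"head"`.
#' @param command_period Seconds between commands (default 2).
#' @param window Analysis window in seconds (default 1); must not exceed
#'   `command_period`.
#' @param piezo_filter Apply the piezo filter chain (default TRUE).
#' @param accel_filter Apply the accelerometer band-pass (default FALSE).
#' @param window_stat Head-interface window summary (see [classify_head()]).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(modality = c("face", "head"), command_period = 2,
                            window = 1, piezo_filter = TRUE, accel_filter = FALSE,
                            window_stat = c("window_mean", "last_sample")) {
  modality <- match.arg(modality)
  window_stat <- match.arg(window_stat)
  if (window > command_period)
    stop("pipeline_config: window must not exceed command_period", call. = FALSE)
  stopifnot(command_period > 0, window > 0)
  structure(list(modality = modality, command_period = command_period,
                 window = window, piezo_filter = piezo_filter,
                 accel_filter = accel_filter, window_stat = window_stat),
            class = "pipeline_config")
}

#' Run the streaming classification pipeline
#'
#' Replays a trace through the real-time loop: every `command_period` seconds
#' one command is emitted from the final `window` seconds of the epoch,
#' after causal filtering and feature extraction. Epoch `k` covers
#' `[k*period, (k+1)*period)` relative to the trace start; a trailing partial
#' epoch is discarded, so `floor(duration / period)` epochs are produced.
#' Filtering is applied causally to the whole stream once (equivalent to
#' sample-by-sample online filtering), so each epoch's command depends only
#' on samples up to its decision instant.
#'
#' @param trace A [piezo_trace()] or [accel_trace()], longer than one period.
#' @param fit The matching calibration (`"face_hmi"` / `"head_hmi"`).
#' @param config A [pipeline_config()]; its modality must match `fit`.
#' @return A data frame of command epochs with columns `index` (0-based),
#'   `start_time` (s) and `command`.
#' @export
run_pipeline <- function(trace, fit, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$modality == "face") {
    if (!inherits(fit, "face_hmi") || !inherits(trace, "piezo_trace"))
      stop("run_pipeline: face modality needs a piezo_trace and a face_hmi calibration",
           call. = FALSE)
  } else {
    if (!inherits(fit, "head_hmi") || !inherits(trace, "accel_trace"))
      stop("run_pipeline: head modality needs an accel_trace and a head_hmi calibration",
           call. = FALSE)
  }
  period <- config$command_period
  if (duration(trace) < period)
    stop("run_pipeline: trace shorter than one command period", call. = FALSE)
  filtered <- if (config$modality == "face" && config$piezo_filter) filter_piezo(trace)
              else if (config$modality == "head" && config$accel_filter) filter_accel(trace)
              else trace
  n_epochs <- floor(duration(trace) / period + 1e-9)
  t0 <- trace$t0
  cmds <- character(n_epochs)
  for (k in seq_len(n_epochs) - 1L) {
    decision_t <- t0 + (k + 1) * period
    w <- trace_window(filtered, decision_t - config$window, decision_t)
    cmds[k + 1L] <- if (config$modality == "face") {
      classify_face(face_features(w, fit))
    } else {
      classify_head(w$channels$ax, w$channels$az, fit, config$window_stat)
    }
  }
  data.frame(index = seq_len(n_epochs) - 1L,
             start_time = t0 + (seq_len(n_epochs) - 1L) * period,
             command = cmds, stringsAsFactors = FALSE)
}

#' Read and write command logs
#'
#' Command epochs are logged as JSON-lines: one object
#' `{"index": k, "start_time": t, "command": "..."}` per line. Round-trips
#' are lossless.
#'
#' @param epochs A command-epoch data frame from [run_pipeline()].
#' @param path File path.
#' @return `log_commands()` returns `path` invisibly; `read_command_log()`
#'   returns the epoch data frame.
#' @export
log_commands <- function(epochs, path) {
  stopifnot(is.data.frame(epochs),
            all(c("index", "start_time", "command") %in% names(epochs)))
  lines <- vapply(seq_len(nrow(epochs)), function(i) {
    jsonlite::toJSON(list(index = epochs$index[i],
                          start_time = epochs$start_time[i],
                          command = epochs$command[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname log_commands
#' @export
read_command_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(index = integer(0), start_time = numeric(0),
                      command = character(0), stringsAsFactors = FALSE))
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(index = vapply(recs, function(r) as.integer(r$index), integer(1)),
             start_time = vapply(recs, function(r) as.numeric(r$start_time), numeric(1)),
             command = vapply(recs, function(r) as.character(r$command), character(1)),
             stringsAsFactors = FALSE)
}
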
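#' Fit a calibration from a generated session
#'
#' Applies the pipeline's preprocessing to the calibration repetitions and
#' fits the matching calibration, so that thresholds are learned on exactly
#' the signal representation the live classifier sees. With
#' `piezo_filter = TRUE` (the default) each face repetition window passes
#' through the piezo filter chain before its maximum is taken; with
#' `accel_filter = FALSE` (the default) head repetitions are used raw, since
#' the 0.1-20 Hz band-pass would strip the tilt plateau the thresholds are
#' calibrated against.
#'
#' @param session A list from [generate_session()] (elements `calibration`
#'   and `trace`), or just the `calibration` repetition list.
#' @param modality `"face"` or `"head"`.
#' @param config A [pipeline_config()] whose filter flags govern the
#'   preprocessing; its modality must match.
#' @param label_map Passed to [fit_head_hmi()] for the head modality.
#' @return A `"face_hmi"` or `"head_hmi"` calibration.
#' @export
fit_session <- function(session, modality = c("face", "head"),
                        config = pipeline_config(modality),
                        label_map = c("auto", "printed")) {
  modality <- match.arg(modality)
  if (config$modality != modality)
    stop("fit_session: config modality does not match", call. = FALSE)
  reps <- if (!is.null(session$calibration)) session$calibration else session
  if (modality == "face") {
    if (isTRUE(config$piezo_filter))
      reps <- lapply(reps, function(r) lapply(r, filter_piezo))
    fit_face_hmi(reps)
  } else {
    if (isTRUE(config$accel_filter))
      reps <- lapply(reps, function(r) lapply(r, filter_accel))
    fit_head_hmi(reps, label_map = match.arg(label_map))
  }
}
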
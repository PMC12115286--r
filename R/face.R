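#' Maximum amplitude of a signal window
#'
#' The sole time-domain feature used by the face-machine interface: the
#' maximum value of the samples in a window.
#'
#' @param window Non-empty numeric vector.
#' @return The maximum element.
#' @export
window_max <- function(window) {
  if (length(window) == 0L)
    stop("window_max: window must be non-empty", call. = FALSE)
  max(window)
}

#' Calibrate the face-machine interface
#'
#' Fits the per-sensor baselines and decision thresholds of the piezoelectric
#' face-machine interface from calibration recordings. Each target sensor
#' (PZ1 = left-eye wink, PZ2 = right-eye wink, PZ3 = tongue push) is activated
#' in exactly five repetitions; the baseline `BP[n]` is the mean of the five
#' per-repetition window maxima, and the thresholds are placed 25% below the
#' baselines:
#' \deqn{TP_n = BP_n - 0.25\,BP_n, \qquad TP_{1,2} = (BP_1+BP_2) - 0.25\,(BP_1+BP_2).}
#' The combined threshold `TP12` guards the both-eye blink (backward) channel.
#'
#' @param reps A list with elements `pz1`, `pz2`, `pz3`, each a list of
#'   exactly 5 repetition windows. A repetition may be a numeric vector
#'   (the target channel's filtered samples) or a [piezo_trace()], from which
#'   the target channel is taken.
#' @return An object of class `"face_hmi"` with elements `BP` (length 3),
#'   `TP` (length 3) and `TP12`.
#' @seealso [predict.face_hmi()], [face_features()], [run_pipeline()]
#' @examples
#' reps <- lapply(1:3, function(n) lapply(1:5, function(r) c(rep(0, 99), n)))
#' names(reps) <- c("pz1", "pz2", "pz3")
#' fit <- fit_face_hmi(reps)
#' coef(fit)
#' @export
fit_face_hmi <- function(reps) {
  sensors <- c("pz1", "pz2", "pz3")
  if (!is.list(reps) || !all(sensors %in% names(reps)))
    stop("fit_face_hmi: reps must be a named list with elements pz1, pz2, pz3",
         call. = FALSE)
  BP <- vapply(sensors, function(s) {
    r <- reps[[s]]
    if (length(r) != 5L)
      stop("fit_face_hmi: exactly 5 repetitions required per sensor (got ",
           length(r), " for ", s, ")", call. = FALSE)
    maxima <- vapply(r, function(w) {
      if (inherits(w, "piezo_trace")) w <- w$channels[[s]]
      window_max(w)
    }, numeric(1))
    mean(maxima)
  }, numeric(1))
  if (any(BP <= 0))
    stop("fit_face_hmi: calibration failure - baseline(s) at or below the noise floor: ",
         paste(sensors[BP <= 0], collapse = ", "), call. = FALSE)
  structure(
    list(BP = unname(BP), TP = unname(0.75 * BP), TP12 = 0.75 * (BP[[1]] + BP[[2]]),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "face_hmi"
  )
}

#' @export
print.face_hmi <- function(x, ...) {
  cat("Face-machine interface calibration\n")
  cat(sprintf("  baselines  BP : %s\n", paste(signif(x$BP, 5), collapse = ", ")))
  cat(sprintf("  thresholds TP : %s  (75%% of baseline)\n",
              paste(signif(x$TP, 5), collapse = ", ")))
  cat(sprintf("  blink  TP12   : %s\n", signif(x$TP12, 5)))
  invisible(x)
}

#' @export
summary.face_hmi <- function(object, ...) {
  out <- data.frame(
    sensor = c("pz1", "pz2", "pz3", "pz1+pz2"),
    action = c("wink left", "wink right", "tongue push", "blink"),
    command = c("TURN_LEFT", "TURN_RIGHT", "FORWARD", "BACKWARD"),
    baseline = c(object$BP, object$BP[1] + object$BP[2]),
    threshold = c(object$TP, object$TP12)
  )
  class(out) <- c("summary.face_hmi", "data.frame")
  out
}

#' @export
coef.face_hmi <- function(object, ...) {
  c(BP1 = object$BP[1], BP2 = object$BP[2], BP3 = object$BP[3],
    TP1 = object$TP[1], TP2 = object$TP[2], TP3 = object$TP[3],
    TP12 = object$TP12)
}

#' Windowed features of the face-machine interface
#'
#' From a 1 s filtered piezo window, computes the per-sensor window maxima
#' `DP[n]` and the rectified threshold excesses
#' \deqn{EP_n = \max(DP_n - TP_n,\, 0), \qquad
#'       EP_{1,2} = \max((DP_1 + DP_2) - TP_{1,2},\, 0).}
#' The combined live statistic for the blink channel is taken additively,
#' `DP12 = DP1 + DP2`, mirroring the additive construction of its threshold.
#'
#' @param window A [piezo_trace()] of exactly 1 s (`sample_rate` samples).
#' @param fit A [fit_face_hmi()] calibration.
#' @return A list with `DP` (length 3) and `EP` (named length 4:
#'   `ep1, ep2, ep3, ep12`), all `EP` components >= 0.
#' @export
face_features <- function(window, fit) {
  stopifnot(inherits(window, "piezo_trace"), inherits(fit, "face_hmi"))
  expect_n <- round(window$sample_rate)
  if (n_samples(window) != expect_n)
    stop(sprintf("face_features: expected a 1 s window (%d samples), got %d",
                 expect_n, n_samples(window)), call. = FALSE)
  DP <- vapply(window$channels, window_max, numeric(1))
  EP <- c(ep1 = max(DP[[1]] - fit$TP[1], 0),
          ep2 = max(DP[[2]] - fit$TP[2], 0),
          ep3 = max(DP[[3]] - fit$TP[3], 0),
          ep12 = max((DP[[1]] + DP[[2]]) - fit$TP12, 0))
  list(DP = unname(DP), EP = EP)
}

#' Classify face-interface features into a command
#'
#' If every rectified excess is zero the command is `IDLE`; otherwise the
#' activated sensor is the argmax over `(EP1, EP2, EP3, EP12)`, with ties
#' broken towards the lowest index, and maps to `TURN_LEFT`, `TURN_RIGHT`,
#' `FORWARD`, `BACKWARD` respectively.
#'
#' @param features A feature list from [face_features()], or a bare numeric
#'   vector of the four `EP` components.
#' @return A single command string.
#' @export
classify_face <- function(features) {
  EP <- if (is.list(features)) features$EP else features
  stopifnot(length(EP) == 4L, all(EP >= 0))
  if (all(EP == 0)) return("IDLE")
  command_levels()[which.max(EP)]
}

#' Predict commands from piezo windows
#'
#' Applies [face_features()] + [classify_face()] to one or more 1 s windows.
#'
#' @param object A `"face_hmi"` calibration.
#' @param newdata A 1 s [piezo_trace()] window, or a list of them.
#' @param type `"command"` (default) or `"features"`.
#' @param ... Unused.
#' @return A character vector of commands, or a list of feature lists.
#' @export
predict.face_hmi <- function(object, newdata, type = c("command", "features"), ...) {
  type <- match.arg(type)
  windows <- if (inherits(newdata, "piezo_trace")) list(newdata) else newdata
  feats <- lapply(windows, face_features, fit = object)
  if (type == "features") return(feats)
  vapply(feats, classify_face, character(1))
}

#' Read and write calibration profiles
#'
#' Calibrations are serialised as small JSON documents so a session can be
#' calibrated once and replayed.
#'
#' @param fit A `"face_hmi"` or `"head_hmi"` object.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly; `read_calibration()`
#'   returns the restored calibration object.
#' @export
write_calibration <- function(fit, path) {
  if (inherits(fit, "face_hmi")) {
    doc <- list(modality = "face", BP = fit$BP, TP = fit$TP, TP12 = fit$TP12,
                created = fit$created)
  } else if (inherits(fit, "head_hmi")) {
    doc <- list(modality = "head",
                Xmax = fit$Xmax, Xmin = fit$Xmin, Zmax = fit$Zmax, Zmin = fit$Zmin,
                Tx = c(fit$Tx_minus, fit$Tx_plus), Tz = c(fit$Tz_minus, fit$Tz_plus),
                label_map = as.list(fit$label_map), created = fit$created)
  } else stop("write_calibration: not a calibration object", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$modality, "face")) {
    structure(list(BP = doc$BP, TP = doc$TP, TP12 = doc$TP12, created = doc$created),
              class = "face_hmi")
  } else if (identical(doc$modality, "head")) {
    structure(list(Xmax = doc$Xmax, Xmin = doc$Xmin, Zmax = doc$Zmax, Zmin = doc$Zmin,
                   Tx_minus = doc$Tx[1], Tx_plus = doc$Tx[2],
                   Tz_minus = doc$Tz[1], Tz_plus = doc$Tz[2],
                   label_map = unlist(doc$label_map), created = doc$created),
              class = "head_hmi")
  } else stop("read_calibration: unknown modality in ", path, call. = FALSE)
}
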
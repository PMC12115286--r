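#' Calibrate the head-machine interface
#'
#' Fits the tilt-detection thresholds of the accelerometer head-machine
#' interface. Each of the four tilt actions (left, right, forward, back) is
#' performed in three repetitions of 1 s windows; the extreme accelerations
#' are taken over all samples of the relevant axis:
#' `Xmax` from the left tilts, `Xmin` from the right tilts, `Zmax` from the
#' forward tilts and `Zmin` from the back tilts. Decision thresholds sit 80%
#' of the half-range inward from each extreme:
#' \deqn{T_{x-} = X_{min} + 0.8\,(X_{max}-X_{min})/2, \qquad
#'       T_{x+} = X_{max} - 0.8\,(X_{max}-X_{min})/2,}
#' and analogously for z, so `Tx_minus < Tx_plus` for every non-degenerate
#' calibration.
#'
#' @param reps A list with elements `left`, `right`, `forward`, `back`, each a
#'   list of exactly 3 repetition windows ([accel_trace()] objects, or numeric
#'   vectors of the relevant axis' samples).
#' @param label_map `"auto"` (default) assigns each decision branch the
#'   command of the action whose calibration data produced that extreme, so
#'   replaying a calibration tilt always yields its own command regardless of
#'   sensor mounting polarity; `"printed"` keeps the literal published rule
#'   (`Ax < Tx- ->` TURN_LEFT, `Ax > Tx+ ->` TURN_RIGHT, `Az < Tz- ->`
#'   FORWARD, `Az > Tz+ ->` BACKWARD).
#' @return An object of class `"head_hmi"` with the four extremes, the four
#'   thresholds and the branch-to-command `label_map`.
#' @seealso [classify_head()], [predict.head_hmi()]
#' @export
fit_head_hmi <- function(reps, label_map = c("auto", "printed")) {
  label_map <- match.arg(label_map)
  actions <- c("left", "right", "forward", "back")
  if (!is.list(reps) || !all(actions %in% names(reps)))
    stop("fit_head_hmi: reps must be a named list with elements left, right, forward, back",
         call. = FALSE)
  axis_of <- c(left = "ax", right = "ax", forward = "az", back = "az")
  pooled <- lapply(actions, function(a) {
    r <- reps[[a]]
    if (length(r) != 3L)
      stop("fit_head_hmi: exactly 3 repetitions required per action (got ",
           length(r), " for ", a, ")", call. = FALSE)
    unlist(lapply(r, function(w) {
      if (inherits(w, "accel_trace")) w$channels[[axis_of[[a]]]] else as.numeric(w)
    }))
  })
  names(pooled) <- actions
  # nominal attribution: the high x side belongs to the left tilts and the
  # high z side to the forward tilts; with a flipped sensor polarity the
  # "auto" map swaps the attribution instead of failing, so the action that
  # produced each extreme is always detected on that extreme's branch
  resolve_axis <- function(hi_act, lo_act, axis) {
    hi <- max(pooled[[hi_act]]); lo <- min(pooled[[lo_act]])
    if (hi > lo)
      list(max = hi, min = lo, high_action = hi_act, low_action = lo_act)
    else if (label_map == "auto" && max(pooled[[lo_act]]) > min(pooled[[hi_act]]))
      list(max = max(pooled[[lo_act]]), min = min(pooled[[hi_act]]),
           high_action = lo_act, low_action = hi_act)
    else
      stop(sprintf("fit_head_hmi: calibration failure - degenerate %s range (min >= max)",
                   axis), call. = FALSE)
  }
  x <- resolve_axis("left", "right", "x")
  z <- resolve_axis("forward", "back", "z")
  Xmax <- x$max; Xmin <- x$min; Zmax <- z$max; Zmin <- z$min
  cmd_of <- c(left = "TURN_LEFT", right = "TURN_RIGHT",
              forward = "FORWARD", back = "BACKWARD")
  lm <- if (label_map == "auto") {
    c(low_x = unname(cmd_of[x$low_action]), high_x = unname(cmd_of[x$high_action]),
      low_z = unname(cmd_of[z$low_action]), high_z = unname(cmd_of[z$high_action]))
  } else {
    c(low_x = "TURN_LEFT", high_x = "TURN_RIGHT",
      low_z = "FORWARD", high_z = "BACKWARD")
  }
  structure(
    list(Xmax = Xmax, Xmin = Xmin, Zmax = Zmax, Zmin = Zmin,
         Tx_minus = Xmin + 0.8 * (Xmax - Xmin) / 2,
         Tx_plus  = Xmax - 0.8 * (Xmax - Xmin) / 2,
         Tz_minus = Zmin + 0.8 * (Zmax - Zmin) / 2,
         Tz_plus  = Zmax - 0.8 * (Zmax - Zmin) / 2,
         label_map = lm,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "head_hmi"
  )
}

#' @export
print.head_hmi <- function(x, ...) {
  cat("Head-machine interface calibration\n")
  cat(sprintf("  x range [%.4g, %.4g] g -> thresholds [%.4g, %.4g] g\n",
              x$Xmin, x$Xmax, x$Tx_minus, x$Tx_plus))
  cat(sprintf("  z range [%.4g, %.4g] g -> thresholds [%.4g, %.4g] g\n",
              x$Zmin, x$Zmax, x$Tz_minus, x$Tz_plus))
  cat(sprintf("  label map: x-low=%s x-high=%s z-low=%s z-high=%s\n",
              x$label_map[["low_x"]], x$label_map[["high_x"]],
              x$label_map[["low_z"]], x$label_map[["high_z"]]))
  invisible(x)
}

#' @export
coef.head_hmi <- function(object, ...) {
  c(Xmin = object$Xmin, Xmax = object$Xmax, Zmin = object$Zmin, Zmax = object$Zmax,
    Tx_minus = object$Tx_minus, Tx_plus = object$Tx_plus,
    Tz_minus = object$Tz_minus, Tz_plus = object$Tz_plus)
}

#' Classify a head-tilt decision window
#'
#' Summarises the current window into scalars `Ax`, `Az` via `window_stat`
#' and applies the ordered decision chain (x-axis rules strictly before
#' z-axis rules, so simultaneous excursions resolve to the x command):
#' `Ax < Tx-`, else `Ax > Tx+`, else `Az < Tz-`, else `Az > Tz+`, else IDLE.
#' The command attached to each branch comes from the calibration's
#' `label_map` (see [fit_head_hmi()]).
#'
#' @param ax,az Numeric samples (or scalars) of the decision window.
#' @param fit A `"head_hmi"` calibration.
#' @param window_stat `"window_mean"` (default; robust to spikes) or
#'   `"last_sample"`.
#' @return A single command string.
#' @export
classify_head <- function(ax, az, fit, window_stat = c("window_mean", "last_sample")) {
  stopifnot(inherits(fit, "head_hmi"))
  window_stat <- match.arg(window_stat)
  Ax <- if (window_stat == "window_mean") mean(ax) else ax[length(ax)]
  Az <- if (window_stat == "window_mean") mean(az) else az[length(az)]
  lm <- fit$label_map
  if (Ax < fit$Tx_minus) lm[["low_x"]]
  else if (Ax > fit$Tx_plus) lm[["high_x"]]
  else if (Az < fit$Tz_minus) lm[["low_z"]]
  else if (Az > fit$Tz_plus) lm[["high_z"]]
  else "IDLE"
}

#' Predict commands from accelerometer windows
#'
#' @param object A `"head_hmi"` calibration.
#' @param newdata A 1 s [accel_trace()] window, or a list of them.
#' @param window_stat Passed to [classify_head()].
#' @param ... Unused.
#' @return A character vector of commands.
#' @export
predict.head_hmi <- function(object, newdata,
                             window_stat = c("window_mean", "last_sample"), ...) {
  window_stat <- match.arg(window_stat)
  windows <- if (inherits(newdata, "accel_trace")) list(newdata) else newdata
  vapply(windows, function(w)
    classify_head(w$channels$ax, w$channels$az, object, window_stat),
    character(1))
}
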
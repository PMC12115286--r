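#' Scripted action sequences
#'
#' An action script is the declarative input to the synthetic generator: an
#' ordered list of timed gesture events standing in for a human participant.
#' Face actions are `wink_left`, `wink_right`, `tongue_push`, `blink`; head
#' actions are `tilt_left`, `tilt_right`, `tilt_forward`, `tilt_back`;
#' `rest` is a no-op placeholder.
#'
#' @param onsets Numeric vector of event onsets in seconds, strictly
#'   increasing, within `[0, duration)`.
#' @param actions Character vector of action names, same length as `onsets`.
#' @param duration Total script duration in seconds.
#' @return A list of class `"action_script"` with a data frame `events` and
#'   the `duration`.
#' @export
action_script <- function(onsets, actions, duration) {
  all_actions <- c(face_actions(), head_actions(), "rest")
  actions <- as.character(actions)
  if (length(onsets) != length(actions))
    stop("action_script: onsets and actions must have the same length", call. = FALSE)
  bad <- setdiff(unique(actions), all_actions)
  if (length(bad))
    stop("action_script: unknown action(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(onsets) && (any(diff(onsets) <= 0)))
    stop("action_script: events must be non-overlapping (strictly increasing onsets)",
         call. = FALSE)
  if (length(onsets) && (min(onsets) < 0 || max(onsets) >= duration))
    stop("action_script: onsets must lie within [0, duration)", call. = FALSE)
  structure(list(events = data.frame(onset = as.numeric(onsets), action = actions,
                                     stringsAsFactors = FALSE),
                 duration = as.numeric(duration)),
            class = "action_script")
}

#' @rdname action_script
#' @export
face_actions <- function() c("wink_left", "wink_right", "tongue_push", "blink")

#' @rdname action_script
#' @export
head_actions <- function() c("tilt_left", "tilt_right", "tilt_forward", "tilt_back")

#' Build a script that issues a command sequence
#'
#' Converts a command sequence into an [action_script()] whose events land
#' inside the decision window of consecutive command epochs (the final
#' `window` seconds of each `period`), so that a clean pipeline run reproduces
#' the sequence one command per epoch.
#'
#' @param commands Character vector of non-IDLE commands.
#' @param modality `"face"` or `"head"`.
#' @param period Command period in seconds (default 2).
#' @param window Decision window length in seconds (default 1).
#' @return An `action_script` of duration `length(commands) * period`.
#' @export
command_script <- function(commands, modality = c("face", "head"),
                           period = 2, window = 1) {
  modality <- match.arg(modality)
  commands <- as_command(commands)
  if (any(commands == "IDLE"))
    stop("command_script: scripted sequences contain no IDLE", call. = FALSE)
  map <- if (modality == "face") {
    c(TURN_LEFT = "wink_left", TURN_RIGHT = "wink_right",
      FORWARD = "tongue_push", BACKWARD = "blink")
  } else {
    c(TURN_LEFT = "tilt_left", TURN_RIGHT = "tilt_right",
      FORWARD = "tilt_forward", BACKWARD = "tilt_back")
  }
  k <- seq_along(commands) - 1L
  # face bursts are short: start shortly after the window opens; head tilts
  # ramp up over ~0.3 s, so start just before it opens to be on the plateau
  onset <- if (modality == "face") k * period + (period - window) + 0.2
           else pmax(k * period + (period - window) - 0.1, 0)
  action_script(onset, unname(map[commands]), duration = length(commands) * period)
}

#' The standard 12-command evaluation sequence
#'
#' The fixed sequence used throughout the evaluation protocol (each of the
#' four commands three times): left, forward, right, backward, forward,
#' right, left, backward, forward, left, backward, right.
#'
#' @return Character vector of 12 commands.
#' @export
evaluation_sequence <- function() {
  c("TURN_LEFT", "FORWARD", "TURN_RIGHT", "BACKWARD", "FORWARD", "TURN_RIGHT",
    "TURN_LEFT", "BACKWARD", "FORWARD", "TURN_LEFT", "BACKWARD", "TURN_RIGHT")
}

#' Synthetic participant model
#'
#' Parameters of the seeded signal generator that stands in for a human
#' participant. Gesture bursts are damped 20 Hz sinusoids of peak amplitude
#' `piezo_amp` (dimensionless; the classification chain is scale-invariant)
#' on the gesture's target sensor(s); head tilts are smooth 0.3 s ramps to a
#' plateau of `sin(tilt_angle)` g on the mapped axis. Rest level is 0 g on
#' both axes (tilt deltas only, no static gravity component). Gaussian noise
#' floors are added throughout.
#'
#' @param piezo_amp Peak burst amplitude per sensor (> 0).
#' @param piezo_noise_sd Piezo noise floor SD (>= 0).
#' @param blink_amp_factor Per-sensor amplitude multiplier during blinks.
#' @param tilt_angle Head tilt angle in degrees.
#' @param accel_noise_sd Accelerometer noise SD in g (>= 0).
#' @param burst_duration Piezo burst duration in seconds.
#' @param tilt_ramp,tilt_hold Tilt ramp and plateau durations in seconds.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `"subject_model"`.
#' @export
subject_model <- function(piezo_amp = 1.0, piezo_noise_sd = 0.02,
                          blink_amp_factor = 1.0, tilt_angle = 30,
                          accel_noise_sd = 0.02, burst_duration = 0.3,
                          tilt_ramp = 0.3, tilt_hold = 1.0, seed = 1L) {
  stopifnot(piezo_amp > 0, piezo_noise_sd >= 0, blink_amp_factor > 0,
            tilt_angle > 0, accel_noise_sd >= 0, burst_duration > 0,
            tilt_ramp >= 0, tilt_hold > 0)
  structure(list(piezo_amp = piezo_amp, piezo_noise_sd = piezo_noise_sd,
                 blink_amp_factor = blink_amp_factor, tilt_angle = tilt_angle,
                 accel_noise_sd = accel_noise_sd, burst_duration = burst_duration,
                 tilt_ramp = tilt_ramp, tilt_hold = tilt_hold,
                 seed = as.integer(seed)),
            class = "subject_model")
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# damped 20 Hz sinusoid normalised to unit peak
burst_shape <- function(n, fs) {
  t <- (seq_len(n) - 1L) / fs
  w <- exp(-t / (n / fs / 3)) * sin(2 * pi * 20 * t)
  w / max(abs(w))
}

#' Generate a synthetic piezo trace
#'
#' Realises a face-action script as a 1000 Hz three-channel piezo trace: each
#' action superposes a damped-sinusoid burst on its target sensor(s)
#' (`wink_left` on PZ1, `wink_right` on PZ2, `tongue_push` on PZ3, `blink` on
#' PZ1 and PZ2 at `blink_amp_factor * piezo_amp`) over a Gaussian noise
#' floor. Deterministic given `subject$seed`.
#'
#' @param script An [action_script()] containing only face actions or rest.
#' @param subject A [subject_model()].
#' @param sample_rate Sampling rate, Hz.
#' @return A [piezo_trace()] of `script$duration` seconds.
#' @export
generate_piezo <- function(script, subject, sample_rate = 1000) {
  stopifnot(inherits(script, "action_script"), inherits(subject, "subject_model"))
  bad <- setdiff(script$events$action, c(face_actions(), "rest"))
  if (length(bad))
    stop("generate_piezo: head action(s) in face script: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- round(script$duration * sample_rate)
  ch <- list(pz1 = numeric(n), pz2 = numeric(n), pz3 = numeric(n))
  nb <- max(2L, round(subject$burst_duration * sample_rate))
  shape <- burst_shape(nb, sample_rate)
  target <- list(wink_left = "pz1", wink_right = "pz2", tongue_push = "pz3",
                 blink = c("pz1", "pz2"))
  for (i in seq_len(nrow(script$events))) {
    act <- script$events$action[i]
    if (act == "rest") next
    i0 <- round(script$events$onset[i] * sample_rate) + 1L
    idx <- i0:min(i0 + nb - 1L, n)
    amp <- if (act == "blink") subject$blink_amp_factor * subject$piezo_amp
           else subject$piezo_amp
    for (s in target[[act]])
      ch[[s]][idx] <- ch[[s]][idx] + amp * shape[seq_along(idx)]
  }
  if (subject$piezo_noise_sd > 0) {
    ch <- with_seed(subject$seed, lapply(ch, function(v)
      v + stats::rnorm(n, sd = subject$piezo_noise_sd)))
  }
  piezo_trace(ch$pz1, ch$pz2, ch$pz3, sample_rate)
}

#' Generate a synthetic accelerometer trace
#'
#' Realises a head-action script as a 200 Hz two-axis acceleration trace:
#' each tilt ramps smoothly (raised-cosine, `tilt_ramp` s) to a plateau of
#' `+/- sin(tilt_angle) * 1 g` on the mapped axis (`tilt_left` +x,
#' `tilt_right` -x, `tilt_forward` +z, `tilt_back` -z), holds for
#' `tilt_hold` s and ramps back to the 0 g rest level; Gaussian noise added.
#' Deterministic given `subject$seed`.
#'
#' @param script An [action_script()] containing only head actions or rest.
#' @param subject A [subject_model()].
#' @param sample_rate Sampling rate, Hz.
#' @return An [accel_trace()] of `script$duration` seconds.
#' @export
generate_accel <- function(script, subject, sample_rate = 200) {
  stopifnot(inherits(script, "action_script"), inherits(subject, "subject_model"))
  bad <- setdiff(script$events$action, c(head_actions(), "rest"))
  if (length(bad))
    stop("generate_accel: face action(s) in head script: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- round(script$duration * sample_rate)
  ax <- numeric(n); az <- numeric(n)
  plateau <- sin(subject$tilt_angle * pi / 180)  # 1 g reference
  sign_axis <- list(tilt_left = c("ax", 1), tilt_right = c("ax", -1),
                    tilt_forward = c("az", 1), tilt_back = c("az", -1))
  nr <- round(subject$tilt_ramp * sample_rate)
  nh <- round(subject$tilt_hold * sample_rate)
  ramp_up <- if (nr > 0) (1 - cos(pi * seq_len(nr) / nr)) / 2 else numeric(0)
  env <- c(ramp_up, rep(1, nh), rev(ramp_up))
  for (i in seq_len(nrow(script$events))) {
    act <- script$events$action[i]
    if (act == "rest") next
    i0 <- round(script$events$onset[i] * sample_rate) + 1L
    idx <- i0:min(i0 + length(env) - 1L, n)
    v <- sign_axis[[act]]
    amp <- as.numeric(v[2]) * plateau
    if (v[1] == "ax") ax[idx] <- ax[idx] + amp * env[seq_along(idx)]
    else az[idx] <- az[idx] + amp * env[seq_along(idx)]
  }
  if (subject$accel_noise_sd > 0) {
    noise <- with_seed(subject$seed + 1L,
                       list(stats::rnorm(n, sd = subject$accel_noise_sd),
                            stats::rnorm(n, sd = subject$accel_noise_sd)))
    ax <- ax + noise[[1]]; az <- az + noise[[2]]
  }
  accel_trace(ax, az, sample_rate)
}

#' Generate a full synthetic session
#'
#' Emits the calibration repetitions the interface protocol prescribes (five
#' 1 s windows per target sensor for the face interface; three 1 s plateau
#' windows per tilt action for the head interface) plus a test trace
#' realising the script. All parts are seeded from `subject$seed`.
#'
#' @param script An [action_script()] (see [command_script()]).
#' @param subject A [subject_model()].
#' @param modality `"face"` or `"head"`.
#' @return A list with `calibration` (repetition lists suitable for
#'   [fit_face_hmi()] / [fit_head_hmi()]) and `trace` (the test trace).
#' @export
generate_session <- function(script, subject, modality = c("face", "head")) {
  modality <- match.arg(modality)
  stopifnot(inherits(subject, "subject_model"))
  if (modality == "face") {
    acts <- c(pz1 = "wink_left", pz2 = "wink_right", pz3 = "tongue_push")
    calibration <- lapply(seq_along(acts), function(j) {
      lapply(1:5, function(r) {
        sub_r <- subject
        sub_r$seed <- subject$seed + 100L * j + r
        generate_piezo(action_script(0.35, acts[[j]], duration = 1), sub_r)
      })
    })
    names(calibration) <- names(acts)
    sub_t <- subject; sub_t$seed <- subject$seed + 7L
    list(calibration = calibration, trace = generate_piezo(script, sub_t))
  } else {
    acts <- c(left = "tilt_left", right = "tilt_right",
              forward = "tilt_forward", back = "tilt_back")
    calibration <- lapply(seq_along(acts), function(j) {
      lapply(1:3, function(r) {
        sub_r <- subject
        sub_r$seed <- subject$seed + 100L * j + r
        tr <- generate_accel(
          action_script(0, acts[[j]], duration = subject$tilt_ramp + subject$tilt_hold + 0.3),
          sub_r)
        # 1 s window on the plateau
        trace_window(tr, subject$tilt_ramp, subject$tilt_ramp + 1)
      })
    })
    names(calibration) <- names(acts)
    sub_t <- subject; sub_t$seed <- subject$seed + 7L
    list(calibration = calibration, trace = generate_accel(script, sub_t))
  }
}
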
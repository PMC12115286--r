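#' Route specifications for the wheelchair simulator
#'
#' A route is an ordered set of 2D checkpoints that must be visited in
#' sequence within a time limit. Two fixture routes mirror the evaluation
#' courses: `route_1()` is a straight 20 m corridor and `route_2()` an
#' L-shaped 35 m course through a cluttered layout, both with five
#' checkpoints A-E and time limits of 360 s and 720 s.
#'
#' @param waypoints A 2-column matrix (x, y in meters) of checkpoints in
#'   visiting order; row names are the checkpoint labels.
#' @param start Numeric `c(x, y)` start position in meters.
#' @param heading Start heading in radians (0 = +x axis).
#' @param time_limit Seconds allowed (> 0).
#' @param checkpoint_radius Capture radius in meters.
#' @return A list of class `"route_spec"`.
#' @export
route_spec <- function(waypoints, start = c(0, 0), heading = 0,
                       time_limit = 360, checkpoint_radius = 0.5) {
  waypoints <- as.matrix(waypoints)
  stopifnot(ncol(waypoints) == 2L, nrow(waypoints) >= 1L,
            time_limit > 0, checkpoint_radius > 0)
  if (is.null(rownames(waypoints)))
    rownames(waypoints) <- LETTERS[seq_len(nrow(waypoints))]
  structure(list(waypoints = waypoints, start = as.numeric(start),
                 heading = as.numeric(heading), time_limit = time_limit,
                 checkpoint_radius = checkpoint_radius),
            class = "route_spec")
}

#' @rdname route_spec
#' @export
route_1 <- function() {
  wp <- cbind(x = c(4, 8, 12, 16, 20), y = rep(0, 5))
  rownames(wp) <- LETTERS[1:5]
  route_spec(wp, start = c(0, 0), heading = 0, time_limit = 360)
}

#' @rdname route_spec
#' @export
route_2 <- function() {
  wp <- cbind(x = c(7, 14, 20, 20, 20), y = c(0, 0, 0, 7, 15))
  rownames(wp) <- LETTERS[1:5]
  route_spec(wp, start = c(0, 0), heading = 0, time_limit = 720)
}

#' Discrete kinematic wheelchair step
#'
#' Per-epoch kinematics of the minimal simulator: `FORWARD` / `BACKWARD`
#' translate by `speed * epoch` meters along the current heading,
#' `TURN_LEFT` / `TURN_RIGHT` rotate in place by `turn_rate` radians, and
#' `IDLE` leaves the state unchanged. Turning never translates. The heading
#' is wrapped to `(-pi, pi]`.
#'
#' @param state A list with `position` (x, y meters) and `heading` (radians).
#' @param command A single command string.
#' @param params A [sim_params()] list.
#' @return The updated state.
#' @export
wheelchair_step <- function(state, command, params = sim_params()) {
  command <- as_command(command)
  stopifnot(length(command) == 1L)
  pos <- state$position; h <- state$heading
  if (command == "FORWARD" || command == "BACKWARD") {
    s <- if (command == "FORWARD") 1 else -1
    pos <- pos + s * params$speed * params$epoch * c(cos(h), sin(h))
  } else if (command == "TURN_LEFT") {
    h <- h + params$turn_rate
  } else if (command == "TURN_RIGHT") {
    h <- h - params$turn_rate
  }
  h <- ((h + pi) %% (2 * pi)) - pi
  if (h <= -pi) h <- h + 2 * pi
  list(position = pos, heading = h)
}

#' @rdname wheelchair_step
#' @param speed Translation speed, m/s (> 0).
#' @param turn_rate Rotation per turning epoch, radians (> 0).
#' @param epoch Command epoch length, seconds (> 0).
#' @export
sim_params <- function(speed = 0.5, turn_rate = pi / 8, epoch = 2) {
  if (speed <= 0 || turn_rate <= 0 || epoch <= 0)
    stop("sim_params: speed, turn_rate and epoch must be positive", call. = FALSE)
  list(speed = speed, turn_rate = turn_rate, epoch = epoch)
}

#' Drive a command stream along a route
#'
#' Consumes commands in order, one per epoch, advancing the wheelchair with
#' [wheelchair_step()]. A checkpoint is captured when the wheelchair comes
#' within `checkpoint_radius` of it (checkpoints must be captured in order).
#' The run ends when the final checkpoint is captured, the stream is
#' exhausted, or the route's time limit elapses.
#'
#' @param route A [route_spec()].
#' @param commands Character vector of commands (the stream).
#' @param params A [sim_params()] list.
#' @return A list with `completed` (logical), `time` (seconds used),
#'   `last_checkpoint` (label or `NA`) and the final `state`.
#' @export
run_route <- function(route, commands, params = sim_params()) {
  stopifnot(inherits(route, "route_spec"))
  commands <- as_command(commands)
  state <- list(position = route$start, heading = route$heading)
  next_cp <- 1L
  n_cp <- nrow(route$waypoints)
  t <- 0
  capture <- function(state, next_cp) {
    while (next_cp <= n_cp &&
           sqrt(sum((state$position - route$waypoints[next_cp, ])^2)) <=
             route$checkpoint_radius)
      next_cp <- next_cp + 1L
    next_cp
  }
  next_cp <- capture(state, next_cp)
  for (cmd in commands) {
    if (next_cp > n_cp || t + params$epoch > route$time_limit + 1e-9) break
    state <- wheelchair_step(state, cmd, params)
    t <- t + params$epoch
    next_cp <- capture(state, next_cp)
  }
  list(completed = next_cp > n_cp,
       time = t,
       last_checkpoint = if (next_cp > 1L) rownames(route$waypoints)[next_cp - 1L]
                         else NA_character_,
       state = state)
}
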
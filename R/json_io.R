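#' JSON serialisation of scripts, subjects and routes
#'
#' Declarative inputs (action scripts, subject models, route specs) are
#' stored as small JSON documents; `inst/extdata/` ships the standard
#' 12-command evaluation script, a default subject and the two fixture
#' routes.
#'
#' @param x The object to write.
#' @param path JSON file path.
#' @return Writers return `path` invisibly; readers return the restored
#'   object.
#' @name json_io
NULL

#' @rdname json_io
#' @export
write_script <- function(x, path) {
  stopifnot(inherits(x, "action_script"))
  jsonlite::write_json(list(events = x$events, duration = x$duration),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname json_io
#' @export
read_script <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(doc$events)
  action_script(ev$onset, ev$action, doc$duration)
}

#' @rdname json_io
#' @export
write_subject <- function(x, path) {
  stopifnot(inherits(x, "subject_model"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname json_io
#' @export
read_subject <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(subject_model, doc)
}

#' @rdname json_io
#' @export
write_route <- function(x, path) {
  stopifnot(inherits(x, "route_spec"))
  jsonlite::write_json(
    list(waypoints = data.frame(label = rownames(x$waypoints),
                                x = x$waypoints[, 1], y = x$waypoints[, 2]),
         start = x$start, heading = x$heading, time_limit = x$time_limit,
         checkpoint_radius = x$checkpoint_radius),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname json_io
#' @export
read_route <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  wp <- cbind(x = doc$waypoints$x, y = doc$waypoints$y)
  rownames(wp) <- doc$waypoints$label
  route_spec(wp, start = doc$start, heading = doc$heading,
             time_limit = doc$time_limit,
             checkpoint_radius = doc$checkpoint_radius)
}

#' Write a reproducibility manifest for a command-line run
#'
#' Every command-line subcommand records its inputs, outputs, options and
#' seed so the run can be reproduced exactly.
#'
#' @param subcommand Subcommand name.
#' @param inputs,outputs Named lists of file paths.
#' @param options Named list of option values (including any seed).
#' @param path Manifest path; defaults to the first output plus
#'   `.manifest.json`.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(subcommand, inputs, outputs, options,
                           path = paste0(outputs[[1]], ".manifest.json")) {
  manifest <- list(
    tool = "hmikit", version = as.character(utils::packageVersion("hmikit")),
    subcommand = subcommand, inputs = inputs, outputs = outputs,
    options = options, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
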
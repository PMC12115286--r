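#' Build a per-command confusion matrix
#'
#' Tallies a command stream against its ground truth into a 4 x 5 count
#' matrix: one row per true (issued) command, one column per emitted command
#' plus a fifth `IDLE` column for trials that resolved to no action. Row sums
#' (including IDLE) equal the number of trials issued per command.
#'
#' @param truth Character vector of issued commands (no IDLE).
#' @param predicted Character vector of emitted commands, same length.
#' @return An object of class `"hmi_confusion"`: the count matrix with a
#'   `trials_per_command` attribute.
#' @export
confusion_from_logs <- function(truth, predicted) {
  truth <- as_command(truth); predicted <- as_command(predicted)
  if (length(truth) != length(predicted))
    stop("confusion_from_logs: truth and predicted must have equal length", call. = FALSE)
  if (any(truth == "IDLE"))
    stop("confusion_from_logs: truth contains IDLE (only issued commands are scored)",
         call. = FALSE)
  lv <- command_levels()
  counts <- table(factor(truth, levels = lv[1:4]), factor(predicted, levels = lv))
  m <- matrix(as.integer(counts), nrow = 4, dimnames = list(true = lv[1:4], output = lv))
  confusion_matrix(m)
}

#' @param counts A 4 x 5 integer matrix (rows: the four commands; columns:
#'   the four commands plus IDLE) to wrap directly, e.g. a published
#'   classification table.
#' @rdname confusion_from_logs
#' @export
confusion_matrix <- function(counts) {
  lv <- command_levels()
  counts <- as.matrix(counts)
  if (ncol(counts) == 4L)  # IDLE column implied by row totals elsewhere; pad 0
    counts <- cbind(counts, 0L)
  stopifnot(nrow(counts) == 4L, ncol(counts) == 5L, all(counts >= 0))
  dimnames(counts) <- list(true = lv[1:4], output = lv)
  structure(counts, class = c("hmi_confusion", "matrix"),
            trials_per_command = rowSums(counts))
}

#' @export
print.hmi_confusion <- function(x, ...) {
  cat("Command confusion matrix (rows = issued, cols = emitted):\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Per-command classification metrics
#'
#' Computes the interface evaluation statistics from a confusion matrix, as
#' percentages per command plus their means:
#' \itemize{
#'   \item success: correct commands over all trials issued for that command
#'     (IDLE outcomes count as failures);
#'   \item precision: `TP / (TP + FP)` down the emitted-command column;
#'   \item sensitivity: `TP / (TP + FN)` across the non-IDLE outcomes of the
#'     issued-command row, so IDLE outcomes shrink only its denominator and
#'     sensitivity is never below success;
#'   \item accuracy: one-vs-rest `(TP + TN) / (TP + TN + FP + FN)` over all
#'     non-IDLE decisions.
#' }
#' A metric with a zero denominator is reported as `NA` (undefined, not 0)
#' and flagged in the `undefined` attribute.
#'
#' @param cm An `"hmi_confusion"` matrix.
#' @param digits Decimal places for the reported percentages (default 1;
#'   `NA` to disable rounding).
#' @return A data frame with one row per command plus a `"Mean"` row and
#'   columns `success`, `precision`, `sensitivity`, `accuracy`.
#' @export
class_metrics <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "hmi_confusion"))
  m <- unclass(cm)
  cmds <- rownames(m)
  trials <- attr(cm, "trials_per_command")
  nonidle <- m[, 1:4, drop = FALSE]
  total <- sum(nonidle)
  TP <- diag(nonidle)
  col_sum <- colSums(nonidle)
  row_sum <- rowSums(nonidle)
  FP <- col_sum - TP
  FN <- row_sum - TP
  TN <- total - TP - FP - FN
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    success = 100 * safe_div(TP, trials),
    precision = 100 * safe_div(TP, TP + FP),
    sensitivity = 100 * safe_div(TP, TP + FN),
    accuracy = 100 * safe_div(TP + TN, TP + TN + FP + FN),
    row.names = cmds
  )
  out <- rbind(out, Mean = colMeans(out, na.rm = TRUE))
  undefined <- which(is.na(as.matrix(out)), arr.ind = TRUE)
  if (!is.na(digits)) out <- round(out, digits)
  attr(out, "undefined") <- undefined
  out
}

#' Mean and population standard deviation
#'
#' Summary convention for per-participant result columns: arithmetic mean and
#' the population (n-denominator) standard deviation.
#'
#' @param values Numeric vector, `n >= 2` for the SD.
#' @return A named numeric vector `c(mean, sd)`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("summary_stats: need at least 2 values for a standard deviation", call. = FALSE)
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Flag metric cells that disagree with a reference grid
#'
#' Recomputes [class_metrics()] from a count matrix and reports every cell
#' whose 1-decimal value differs from a supplied reference grid (e.g. a
#' published metrics table whose own counts do not reproduce it). Used by the
#' command-line `evaluate --strict-ref` mode.
#'
#' @param cm An `"hmi_confusion"` matrix.
#' @param reference A data frame or matrix shaped like the [class_metrics()]
#'   output (commands + Mean rows; success/precision/sensitivity/accuracy
#'   columns).
#' @return A data frame of discrepancies (row, metric, recomputed, reference);
#'   zero rows when everything agrees.
#' @export
reference_discrepancies <- function(cm, reference) {
  got <- class_metrics(cm, digits = 1)
  reference <- as.data.frame(reference)
  stopifnot(identical(dim(got), dim(reference)))
  out <- data.frame(row = character(0), metric = character(0),
                    recomputed = numeric(0), reference = numeric(0))
  for (i in seq_len(nrow(got))) for (j in seq_len(ncol(got))) {
    g <- got[i, j]; r <- as.numeric(reference[i, j])
    if (is.na(g) || is.na(r)) next
    if (abs(g - r) > 0.05 + 1e-9)
      out <- rbind(out, data.frame(row = rownames(got)[i], metric = names(got)[j],
                                   recomputed = g, reference = r))
  }
  out
}
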
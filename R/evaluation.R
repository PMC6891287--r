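#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return An object of class `"confusion_counts"`: list with integers `TP`,
#'   `FP`, `TN`, `FN` (summing to the number of items).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (!all(c(y_true, y_pred) %in% c(0, 1)))
    stop("labels must be 0 or 1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Precision, sensitivity, specificity and accuracy
#'
#' The four confusion-count metrics: precision `TP/(TP+FP)`, sensitivity
#' (true positive rate) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/total`. A metric with a zero denominator is reported as `NA`
#' (explicitly undefined), never silently as 0.
#'
#' @param cm A [confusion()] result.
#' @return Named numeric vector `precision`, `sensitivity`, `specificity`,
#'   `accuracy` (NA where undefined).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(precision = ratio(cm$TP, cm$TP + cm$FP),
    sensitivity = ratio(cm$TP, cm$TP + cm$FN),
    specificity = ratio(cm$TN, cm$TN + cm$FP),
    accuracy = ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN))
}

#' ROC curve and area under it
#'
#' Computes the receiver operating characteristic: for thresholds at the
#' unique score values (ties grouped at one threshold), the false positive
#' rate `FP/(FP+TN)` and true positive rate `TP/(TP+FN)` of the classifier
#' that predicts positive when `score >= threshold`. The curve starts at
#' (0,0), ends at (1,1), and the AUROC is its trapezoidal area -- equal to
#' the probability that a random positive scores above a random negative
#' (ties counted half).
#'
#' @param y_true Binary (0/1) vector containing both classes.
#' @param scores Numeric scores, larger meaning more positive.
#' @return An object of class `"roc_curve"`: list with `fpr`, `tpr`,
#'   `thresholds` (descending, with a leading `Inf`) and `auroc`.
#' @export
roc_auroc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores lengths differ")
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0 or 1")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate input: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie
  tp <- cumsum(y == 1)[grp_last]
  fp <- cumsum(y == 0)[grp_last]
  fpr <- c(0, fp / n0)
  tpr <- c(0, tp / n1)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[grp_last]), auroc = auroc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUROC = %.4f\n",
              length(x$thresholds), x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Macro-averaged evaluation report over the six contrasts
#'
#' Assembles the per-contrast confusion metrics and AUROC into one table and
#' appends their unweighted means across the six one-vs-rest contrasts.
#'
#' @param per_contrast Named list (keys HS, GS, LT, HD, RP, RL), each element
#'   a list with `metrics` (from [classification_metrics()]), `roc` (from
#'   [roc_auroc()]) and optionally `n` (test-set size).
#' @return An object of class `"eval_report"`: list with `table` (per-event
#'   data frame plus a `macro` row of unweighted means) and `rocs` (the ROC
#'   curves).
#' @export
macro_report <- function(per_contrast) {
  missing <- setdiff(gal_events, names(per_contrast))
  if (length(missing))
    stop("coverage error: missing contrast(s): ",
         paste(missing, collapse = ", "))
  rows <- lapply(gal_events, function(ev) {
    x <- per_contrast[[ev]]
    data.frame(event = ev, precision = x$metrics[["precision"]],
               sensitivity = x$metrics[["sensitivity"]],
               specificity = x$metrics[["specificity"]],
               accuracy = x$metrics[["accuracy"]],
               auroc = x$roc$auroc,
               n = if (is.null(x$n)) NA_integer_ else x$n)
  })
  tab <- do.call(rbind, rows)
  macro <- data.frame(event = "macro",
                      t(colMeans(tab[, 2:6])),
                      n = sum(tab$n))
  names(macro) <- names(tab)
  structure(list(table = rbind(tab, macro),
                 rocs = lapply(per_contrast[gal_events], `[[`, "roc")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Per-contrast evaluation (one-vs-rest):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write / read an evaluation report
#'
#' The per-event metric table round-trips through CSV exactly (values
#' re-read equal the originals at the written precision).
#'
#' @param report An [macro_report()] result.
#' @param path Output CSV path.
#' @return `write_report` returns `path` invisibly; `read_report_table`
#'   returns the table data frame.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  data.table::fwrite(report$table, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
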
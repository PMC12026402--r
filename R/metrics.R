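# Confusion matrices and the standard two-class evaluation statistics:
# accuracy = 100 (TP+TN)/(TP+TN+FP+FN), precision = 100 TP/(TP+FP),
# recall = 100 TP/(TP+FN), F1 = harmonic mean of precision and recall,
# plus support-weighted averages. Percentages are reported half-up at 1 dp
# (table convention) and accuracy additionally at 2 dp; undefined metrics
# (zero denominators) are reported as missing, never as 0, so they cannot
# silently inflate weighted averages.

#' Build a two-class confusion matrix
#'
#' @param true,predicted equal-length label vectors over
#'   \{positive, negative\} classes.
#' @param positive name of the positive class.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(true, predicted, positive) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  true <- as.character(true); predicted <- as.character(predicted)
  classes <- unique(c(true, predicted))
  if (!positive %in% classes)
    stop("positive class not present in labels: ", positive)
  if (length(classes) > 2L)
    stop("more than two classes: ", paste(classes, collapse = ", "))
  negative <- setdiff(classes, positive)
  if (length(negative) == 0L) negative <- paste0("not_", positive)
  isPos <- true == positive
  predPos <- predicted == positive
  new("ConfusionMatrix",
      tp = sum(isPos & predPos), fp = sum(!isPos & predPos),
      tn = sum(!isPos & !predPos), fn = sum(isPos & !predPos),
      positive = positive, negative = negative)
}

#' @rdname confusionMatrix
#' @param tp,fp,tn,fn integer counts.
#' @param negative negative class name.
#' @export
confusionMatrixFromCounts <- function(tp, fp, tn, fn,
                                      positive = "cd41_pos",
                                      negative = "cd41_neg") {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      positive = positive, negative = negative)
}

cmTotal <- function(cm) cm@tp + cm@fp + cm@tn + cm@fn

#' Accuracy in percent
#' @param cm a [ConfusionMatrix-class].
#' @return unrounded percentage.
#' @export
accuracyPct <- function(cm) {
  if (cmTotal(cm) == 0L) stop("empty confusion matrix")
  100 * (cm@tp + cm@tn) / cmTotal(cm)
}

#' Precision in percent
#' @param cm a [ConfusionMatrix-class].
#' @return unrounded percentage, `NA` (with a warning) when TP+FP = 0.
#' @export
precisionPct <- function(cm) {
  if (cm@tp + cm@fp == 0L) {
    warning("precision undefined: no predicted positives")
    return(NA_real_)
  }
  100 * cm@tp / (cm@tp + cm@fp)
}

#' Recall (sensitivity) in percent
#' @param cm a [ConfusionMatrix-class].
#' @return unrounded percentage, `NA` (with a warning) when TP+FN = 0.
#' @export
recallPct <- function(cm) {
  if (cm@tp + cm@fn == 0L) {
    warning("recall undefined: no true positives in the data")
    return(NA_real_)
  }
  100 * cm@tp / (cm@tp + cm@fn)
}

#' F1 score from precision and recall percentages
#'
#' Harmonic mean `2 p r / (p + r)`, on the percent scale.
#' @param precision,recall percentages.
#' @return percentage; 0 with a warning when both inputs are 0.
#' @export
f1Pct <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) {
    warning("F1 undefined at precision = recall = 0; reporting 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Support-weighted average of per-class metrics
#'
#' @param values per-class metric values (percent).
#' @param supports per-class event counts.
#' @return unrounded support-weighted mean.
#' @export
weightedAverage <- function(values, supports) {
  if (sum(supports) <= 0) stop("total support must be positive")
  if (any(supports < 0)) stop("supports must be nonnegative")
  sum(values * supports) / sum(supports)
}

# metrics of the negative class = the matrix with roles swapped
swapCM <- function(cm) {
  new("ConfusionMatrix", tp = cm@tn, fp = cm@fn, tn = cm@tp, fn = cm@fp,
      positive = cm@negative, negative = cm@positive)
}

#' Full metrics report for a confusion matrix
#'
#' Per-class support/precision/recall/F1 rows (half-up, 1 dp), the
#' support-weighted average row, overall accuracy at 2 dp, and the row-
#' and column-normalized matrix views (recall and precision views).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return a [MetricsReport-class].
#' @export
metricsReport <- function(cm) {
  perClass <- function(m) {
    p <- suppressWarnings(precisionPct(m))
    r <- suppressWarnings(recallPct(m))
    f <- if (is.na(p) || is.na(r)) NA_real_ else f1Pct(p, r)
    c(support = m@tp + m@fn, precision = p, recall = r, f1 = f)
  }
  pos <- perClass(cm); neg <- perClass(swapCM(cm))
  supports <- c(pos[["support"]], neg[["support"]])
  wavg <- function(a, b) {
    if (is.na(a) || is.na(b)) NA_real_ else weightedAverage(c(a, b), supports)
  }
  tab <- data.frame(
    class = c(cm@positive, cm@negative, "weighted_average"),
    support = c(supports, sum(supports)),
    precision = halfUp(c(pos[["precision"]], neg[["precision"]],
                         wavg(pos[["precision"]], neg[["precision"]])), 1),
    recall = halfUp(c(pos[["recall"]], neg[["recall"]],
                      wavg(pos[["recall"]], neg[["recall"]])), 1),
    f1 = halfUp(c(pos[["f1"]], neg[["f1"]],
                  wavg(pos[["f1"]], neg[["f1"]])), 1))
  counts <- matrix(c(cm@tp, cm@fn, cm@fp, cm@tn), 2L, byrow = TRUE,
                   dimnames = list(true = c(cm@positive, cm@negative),
                                   predicted = c(cm@positive, cm@negative)))
  rowNorm <- counts / ifelse(rowSums(counts) > 0, rowSums(counts), NA)
  colNorm <- sweep(counts, 2L,
                   ifelse(colSums(counts) > 0, colSums(counts), NA), "/")
  new("MetricsReport", table = tab,
      accuracy = halfUp(accuracyPct(cm), 2),
      rowNorm = rowNorm, colNorm = colNorm, cm = cm)
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport: accuracy", object@accuracy, "%\n")
  print(object@table, row.names = FALSE)
})

#' Serialize a metrics report to JSON (lossless round trip)
#'
#' @param report a [MetricsReport-class].
#' @param path output path; when `NULL` the JSON string is returned.
#' @export
writeMetricsReport <- function(report, path = NULL) {
  cm <- report@cm
  obj <- list(accuracy_pct = report@accuracy,
              table = report@table,
              row_normalized = as.data.frame(report@rowNorm),
              col_normalized = as.data.frame(report@colNorm),
              counts = list(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn,
                            positive = cm@positive, negative = cm@negative))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetricsReport
#' @param json JSON string or path produced by [writeMetricsReport()].
#' @export
readMetricsReport <- function(json) {
  l <- jsonlite::fromJSON(json)
  cm <- confusionMatrixFromCounts(l$counts$tp, l$counts$fp, l$counts$tn,
                                  l$counts$fn, l$counts$positive,
                                  l$counts$negative)
  metricsReport(cm)
}
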
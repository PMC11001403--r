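#' Confusion matrix of a binary good/bad evaluation
#'
#' Compares predicted labels against the annotated truth with `good` as
#' the positive class: TP = good predicted good, TN = bad predicted bad,
#' FP = bad predicted good, FN = good predicted bad.
#'
#' @param yTrue,yPred character vectors of `good`/`bad`, equal length.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(yTrue, yPred) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(yTrue), length(yPred)))
  if (!length(yTrue)) stop("need at least one label pair")
  if (!all(c(yTrue, yPred) %in% c("good", "bad")))
    stop("labels must be binary 'good'/'bad'")
  new("ConfusionMatrix",
      tp = sum(yTrue == "good" & yPred == "good"),
      tn = sum(yTrue == "bad" & yPred == "bad"),
      fp = sum(yTrue == "bad" & yPred == "good"),
      fn = sum(yTrue == "good" & yPred == "bad"))
}

#' Classification report: accuracy, misclassification, precision, recall,
#' F1 and support
#'
#' Computes, from the confusion matrix (positive class = good):
#' accuracy = (TP + TN) / total and its complement the misclassification
#' rate = (FP + FN) / total; per-class precision (fraction of predicted
#' instances of the class that are actual), recall (fraction of actual
#' instances identified), F1 (harmonic mean of precision and recall),
#' support (actual occurrences of the class), and the per-class
#' misclassification rate (1 - recall: the fraction of that class's
#' frames sorted into the wrong bin). The bad-class metrics are the same
#' formulas with the class roles swapped. All rates are fractions in
#' \[0, 1\]. A ratio with zero denominator (e.g. precision when nothing
#' was predicted positive) is `NA` and listed in the report's
#' `undefined` slot, never silently 0.
#'
#' @param yTrue,yPred character vectors of `good`/`bad`, or a
#'   [ConfusionMatrix-class] as the first argument.
#' @return A [ClassificationReport-class].
#' @examples
#' r <- classificationReport(c("good", "good", "bad"), c("good", "bad", "bad"))
#' r@accuracy
#' @export
classificationReport <- function(yTrue, yPred = NULL) {
  cm <- if (is(yTrue, "ConfusionMatrix")) yTrue else
    confusionMatrix(yTrue, yPred)
  tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  total <- tp + tn + fp + fn

  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (tp + tn) / total
  misclassification <- (fp + fn) / total

  precG <- ratio(tp, tp + fp, "precision.good")
  recG <- ratio(tp, tp + fn, "recall.good")
  f1G <- .f1(precG, recG)
  precB <- ratio(tn, tn + fn, "precision.bad")
  recB <- ratio(tn, tn + fp, "recall.bad")
  f1B <- .f1(precB, recB)
  if (is.na(f1G)) undefined <- c(undefined, "f1.good")
  if (is.na(f1B)) undefined <- c(undefined, "f1.bad")

  perClass <- data.frame(
    class = c("good", "bad"),
    precision = c(precG, precB),
    recall = c(recG, recB),
    f1 = c(f1G, f1B),
    support = c(tp + fn, tn + fp),
    misclassification = c(if (is.na(recG)) NA_real_ else 1 - recG,
                          if (is.na(recB)) NA_real_ else 1 - recB),
    stringsAsFactors = FALSE)

  new("ClassificationReport", accuracy = accuracy,
      misclassification = misclassification, perClass = perClass,
      undefined = unique(undefined), cm = cm)
}

.f1 <- function(p, r) {
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Serialize a classification report
#'
#' @param report a [ClassificationReport-class].
#' @param path optional file; when given, an aligned plain-text rendering
#'   plus a machine-readable JSON block are written there.
#' @return named list of all report fields (rates as fractions),
#'   invisibly when `path` is given.
#' @export
reportFields <- function(report, path = NULL) {
  stopifnot(is(report, "ClassificationReport"))
  pc <- report@perClass
  out <- list(
    accuracy = report@accuracy,
    misclassification = report@misclassification,
    precision.good = pc$precision[1L], recall.good = pc$recall[1L],
    f1.good = pc$f1[1L], support.good = pc$support[1L],
    misclassification.good = pc$misclassification[1L],
    precision.bad = pc$precision[2L], recall.bad = pc$recall[2L],
    f1.bad = pc$f1[2L], support.bad = pc$support[2L],
    misclassification.bad = pc$misclassification[2L],
    tp = report@cm@tp, tn = report@cm@tn,
    fp = report@cm@fp, fn = report@cm@fn,
    undefined = report@undefined)
  if (!is.null(path)) {
    txt <- utils::capture.output(show(report))
    writeLines(c(txt, "", jsonlite::toJSON(out, auto_unbox = TRUE,
                                           digits = NA, null = "null")), path)
    return(invisible(out))
  }
  out
}
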
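## Segmentation accuracy against ground truth: pixel confusion counts and
## the four derived overlap scores. R is the result set, T the true set:
##   TP = |R n T|, TN = |complement(R u T)|, FP = |R n ~T|, FN = |~R n T|
##   DSC  = 2 TP / ((FP + TP) + (TP + FN))
##   Jaccard = TP / (FP + TP + FN)
##   Sensitivity = TP / (TP + FN),  Specificity = TN / (TN + FP)

#' Pixel confusion counts of a result mask against truth
#'
#' @param result logical result mask R.
#' @param truth logical ground-truth mask T.
#' @param evalMask optional logical mask restricting the counted pixels
#'   (default: the whole grid).
#' @return named integer vector (tp, tn, fp, fn) summing to the number of
#'   evaluated pixels.
#' @export
confusionCounts <- function(result, truth, evalMask = NULL) {
  if (!identical(dim(result), dim(truth)))
    stop("result and truth must share one shape")
  if (!is.null(evalMask)) {
    if (!identical(dim(evalMask), dim(truth)))
      stop("evalMask must share the masks' shape")
    result <- result[evalMask]
    truth <- truth[evalMask]
  }
  c(tp = sum(result & truth), tn = sum(!result & !truth),
    fp = sum(result & !truth), fn = sum(!result & truth))
}

scoreOrNaN <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator", call. = FALSE)
    return(NaN)
  }
  num / den
}

#' Score a segmentation against ground truth
#'
#' Computes the confusion counts and the four overlap scores. Any score
#' with a zero denominator (e.g. specificity when truth covers the whole
#' evaluated region) is reported as \code{NaN} with a warning.
#'
#' @inheritParams confusionCounts
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateSegmentation <- function(result, truth, evalMask = NULL) {
  ct <- confusionCounts(result, truth, evalMask)
  tp <- ct[["tp"]]; tn <- ct[["tn"]]; fp <- ct[["fp"]]; fn <- ct[["fn"]]
  new("MetricsReport", tp = tp, tn = tn, fp = fp, fn = fn,
      dsc = scoreOrNaN(2 * tp, (fp + tp) + (tp + fn), "DSC"),
      jaccard = scoreOrNaN(tp, fp + tp + fn, "Jaccard"),
      sensitivity = scoreOrNaN(tp, tp + fn, "sensitivity"),
      specificity = scoreOrNaN(tn, tn + fp, "specificity"))
}

#' Coerce a metrics report to a one-row data.frame
#'
#' @param x a \linkS4class{MetricsReport}.
#' @param ... ignored.
#' @return one-row data.frame (TP TN FP FN DSC Jaccard Sens Spec).
#' @export
as.data.frame.MetricsReport <- function(x, ...) {
  data.frame(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn, dsc = x@dsc,
             jaccard = x@jaccard, sensitivity = x@sensitivity,
             specificity = x@specificity)
}
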
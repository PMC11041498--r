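# The four scoring metrics. R2/CPM for regression tasks, AUROC/AUPRC for
# classification tasks; all four are bounded above by 1.

#' Prediction metrics
#'
#' `cpm()` is one minus the relative mean absolute error (Cumming
#' predictive measure): `1 - sum(|y - yhat|) / sum(|y - mean(y)|)`, the
#' mean-absolute analogue of R-squared, with the mean of the evaluation set
#' as reference predictor (`reference = "median"` substitutes the median).
#' `r2()` is the usual coefficient of determination. `auroc()` is the area
#' under the ROC curve, computed as the Mann-Whitney statistic with ties
#' counted one half. `auprc()` is the area under the precision-recall curve
#' in the step-integral (average precision) convention
#' `sum((recall_i - recall_{i-1}) * precision_i)` over descending score
#' thresholds -- not the trapezoid, which gives different (optimistic)
#' values on coarse curves.
#'
#' @param y,yhat numeric vectors of equal length (>= 2); `y` must not be
#'   constant.
#' @param labels binary 0/1 vector; both classes must be present.
#' @param scores numeric classifier scores, larger = more positive.
#' @param reference reference predictor for `cpm` (mean or median).
#' @return a single number; `auroc`/`auprc` lie in `[0, 1]`, `r2`/`cpm` are
#'   at most 1 and can be negative for models worse than the reference.
#' @examples
#' cpm(c(0, 2, 4), c(1, 2, 3))   # 0.5
#' auroc(c(1, 0), c(0.9, 0.1))   # 1
#' @export
cpm <- function(y, yhat, reference = c("mean", "median")) {
  reference <- match.arg(reference)
  check_reg_inputs(y, yhat)
  ref <- if (reference == "mean") mean(y) else median(y)
  denom <- sum(abs(y - ref))
  if (denom == 0) stop("cpm undefined: y is constant", call. = FALSE)
  1 - sum(abs(y - yhat)) / denom
}

#' @rdname cpm
#' @export
r2 <- function(y, yhat) {
  check_reg_inputs(y, yhat)
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("r2 undefined: y is constant", call. = FALSE)
  1 - sum((y - yhat)^2) / denom
}

check_reg_inputs <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(y) || anyNA(yhat)) stop("NA in inputs", call. = FALSE)
  invisible(NULL)
}

check_cls_inputs <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores lengths differ", call. = FALSE)
  if (anyNA(labels) || anyNA(scores)) stop("NA in inputs", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  invisible(NULL)
}

#' @rdname cpm
#' @export
auroc <- function(labels, scores) {
  check_cls_inputs(labels, scores)
  r <- rank(scores)                       # midranks handle ties as 1/2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname cpm
#' @export
auprc <- function(labels, scores) {
  check_cls_inputs(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  n1 <- sum(labels == 1)
  tp <- cumsum(labels == 1)
  fp <- cumsum(labels == 0)
  # evaluate at each distinct threshold (last index of each tied block)
  last <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}
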
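#' Binary confusion counts
#'
#' Tallies TP/TN/FP/FN with positive class 1.
#'
#' @param y_true 0/1 truth labels.
#' @param y_pred 0/1 predicted labels.
#' @return list of class \code{"confusion_counts"}.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("confusion: label vectors have different lengths")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stop("confusion: labels must be binary 0/1")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP =", x$TP, " TN =", x$TN,
      " FP =", x$FP, " FN =", x$FN, "\n")
  invisible(x)
}

safe_ratio <- function(num, den, flags, name) {
  if (den == 0) {
    flags$degenerate <- c(flags$degenerate, name)
    list(value = 0, flags = flags)
  } else list(value = num / den, flags = flags)
}

#' Confusion-matrix metric suite
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), recall/sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), F1 = 2PR/(P+R), negative predictive
#' value TN/(TN+FN), Matthews correlation coefficient, fall-out rate
#' FP/(FP+TN) and miss rate FN/(FN+TP). Ratios with a zero denominator are
#' reported as 0 and named in the \code{degenerate} attribute rather than
#' raising.
#'
#' @param c a \code{\link{confusion}} result.
#' @return list of class \code{"metric_report"}; metric names above, with a
#'   \code{degenerate} character attribute naming any flagged ratios.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("classification_metrics: all counts are zero")
  flags <- list(degenerate = character(0))
  p <- safe_ratio(c$TP, c$TP + c$FP, flags, "precision"); flags <- p$flags
  r <- safe_ratio(c$TP, c$TP + c$FN, flags, "recall"); flags <- r$flags
  sp <- safe_ratio(c$TN, c$TN + c$FP, flags, "specificity"); flags <- sp$flags
  npv <- safe_ratio(c$TN, c$TN + c$FN, flags, "npv"); flags <- npv$flags
  f1 <- safe_ratio(2 * p$value * r$value, p$value + r$value, flags, "f1")
  flags <- f1$flags
  mcc_den <- sqrt(c$TP + c$FP) * sqrt(c$TP + c$FN) *
    sqrt(c$TN + c$FP) * sqrt(c$TN + c$FN)
  mcc <- safe_ratio(as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN,
                    mcc_den, flags, "mcc")
  flags <- mcc$flags
  rep <- list(accuracy = (c$TP + c$TN) / total,
              precision = p$value,
              recall_sensitivity = r$value,
              specificity = sp$value,
              f1 = f1$value,
              npv = npv$value,
              mcc = mcc$value,
              fall_out = 1 - sp$value,
              miss_rate = 1 - r$value)
  if ("specificity" %in% flags$degenerate) rep$fall_out <- 0
  if ("recall" %in% flags$degenerate) rep$miss_rate <- 0
  attr(rep, "degenerate") <- flags$degenerate
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("Classification metrics:\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], digits = digits)))
  dg <- attr(x, "degenerate")
  if (length(dg)) cat("  (degenerate denominators:",
                      paste(dg, collapse = ", "), ")\n")
  invisible(x)
}

#' ROC curve and area under it
#'
#' Thresholds at every distinct score; the ROC is traversed from the most
#' to the least confident prediction and the area computed by the trapezoid
#' rule, which handles tied scores by rank-averaging and therefore equals
#' the pairwise-concordance probability that a random positive outscores a
#' random negative.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores real-valued scores, higher = more positive.
#' @return list with \code{roc} (data.frame of fpr/tpr points, one per
#'   distinct threshold plus the origin) and \code{auc}.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("roc_auc: length mismatch")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; sc <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)  # last index of each tie group
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
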
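#' ROC curve from two-group feature tests
#'
#' Builds the receiver operating characteristic of classifying features as
#' differentially expressed at varying significance thresholds: the true
#' positive rate is the fraction of truly changing features called at a
#' threshold, the false positive rate the fraction of unchanged features
#' called at the same threshold.
#'
#' @param pvalues Numeric vector of per-feature p-values.
#' @param is_positive Logical vector: `TRUE` for features with a real group
#'   difference.
#' @return List with `points` (data frame `threshold`, `tpr`, `fpr`,
#'   monotone non-decreasing) and `auc` (trapezoidal area).
#' @export
roc_from_groups <- function(pvalues, is_positive) {
  keep <- is.finite(pvalues) & !is.na(is_positive)
  p <- pvalues[keep]; pos <- is_positive[keep]
  if (!any(pos) || all(pos)) stop("need both positive and negative features")
  th <- c(sort(unique(p)), Inf)
  tpr <- vapply(th, function(t) mean(p[pos] <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(p[!pos] <= t), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(c(0, fpr)) * (tpr + c(0, utils::head(tpr, -1))) / 2)
  list(points = data.frame(threshold = th[o], tpr = tpr, fpr = fpr),
       auc = auc)
}

#' Per-feature two-sample Welch tests on log2 intensities
#'
#' A plain Welch t-test per feature between two channel groups of a
#' (feature x channel) intensity matrix, on log2-transformed values.
#'
#' @param mat Numeric matrix, features in rows.
#' @param channels_a,channels_b Column names of the two groups (>= 2 each).
#' @return Numeric vector of p-values (NA where a group has < 2 finite
#'   values).
#' @export
welch_group_pvalues <- function(mat, channels_a, channels_b) {
  la <- log2(mat[, channels_a, drop = FALSE])
  lb <- log2(mat[, channels_b, drop = FALSE])
  vapply(seq_len(nrow(mat)), function(i) {
    a <- la[i, ][is.finite(la[i, ])]
    b <- lb[i, ][is.finite(lb[i, ])]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(c(a, b)) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, numeric(1))
}
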
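#' Predictability metrics for regression-based genomic prediction
#'
#' `metric_pearson()` and `metric_spearman()` are the standard
#' product-moment and rank correlations between predicted and observed
#' values; with fewer than 3 pairs or a constant vector the value is
#' undefined and `NA` is returned (never zero), so that degenerate
#' cross-validation folds can be excluded from averages rather than bias
#' them.
#'
#' @param yhat predicted values.
#' @param y observed values.
#' @return A correlation in \[-1, 1\], or `NA` when undefined.
#' @export
metric_pearson <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  if (length(y) < 3 || stats::sd(yhat) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(yhat, y)
}

#' @rdname metric_pearson
#' @export
metric_spearman <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  if (length(y) < 3 || stats::sd(yhat) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(yhat, y, method = "spearman")
}

#' Matched rate of top-ranked accessions
#'
#' The fraction of the top `ceiling(fraction * n)` accessions by observed
#' value that are recovered in the top set by predicted value — the
#' selection-relevant view of predictability ("matched rate of top 30% /
#' 15%"). Ranking ties are broken by input (accession) order.
#'
#' @param yhat predicted values.
#' @param y observed values.
#' @param fraction top fraction, e.g. 0.30 or 0.15.
#' @return A value in \[0, 1\].
#' @export
metric_top_match <- function(yhat, y, fraction = 0.30) {
  stopifnot(length(yhat) == length(y), fraction > 0, fraction <= 1)
  n <- length(y)
  s <- ceiling(fraction * n)
  top_hat <- order(-yhat, seq_len(n))[seq_len(s)]
  top_obs <- order(-y, seq_len(n))[seq_len(s)]
  length(intersect(top_hat, top_obs)) / s
}

#' Classification accuracy
#'
#' Fraction of exact label matches (the multiclass generalisation of
#' "true positives plus true negatives over all samples").
#'
#' @param pred_labels predicted labels.
#' @param true_labels observed labels, same length.
#' @return A value in \[0, 1\].
#' @export
metric_accuracy <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels))
  mean(as.character(pred_labels) == as.character(true_labels))
}

#' Area under the ROC curve from class scores
#'
#' Binary problems use the rank-based (Mann-Whitney) AUC via \pkg{pROC};
#' multiclass problems are macro-averaged one-vs-rest: each class present
#' in the truth is scored against the rest using its score column, and the
#' per-class AUCs are averaged. Invariant to any strictly increasing
#' transform of the scores.
#'
#' @param scores samples x classes score matrix with column names matching
#'   the class labels (e.g. from [predict_scores()]).
#' @param true_labels observed labels; at least two classes must be
#'   present.
#' @return A value in \[0, 1\].
#' @export
metric_auc <- function(scores, true_labels) {
  scores <- as.matrix(scores)
  true_labels <- as.character(true_labels)
  stopifnot(nrow(scores) == length(true_labels))
  present <- unique(true_labels)
  if (length(present) < 2) stop("AUC undefined: truth contains a single class")
  if (is.null(colnames(scores))) stop("scores must have class column names")
  if (!all(present %in% colnames(scores)))
    stop("truth contains classes absent from the score columns")
  if (length(present) == 2 && ncol(scores) == 2) {
    cls <- colnames(scores)[2]
    r <- pROC::roc(response = factor(true_labels == cls, levels = c(FALSE, TRUE)),
                   predictor = scores[, cls], quiet = TRUE, direction = "<")
    return(as.numeric(pROC::auc(r)))
  }
  aucs <- vapply(present, function(cls) {
    r <- pROC::roc(response = factor(true_labels == cls, levels = c(FALSE, TRUE)),
                   predictor = scores[, cls], quiet = TRUE, direction = "<")
    as.numeric(pROC::auc(r))
  }, numeric(1))
  mean(aucs)
}

#' Map regression predictions onto ordinal categories by quantile
#'
#' Assigns predicted continuous values to classes using the observed
#' class proportions of the corresponding descriptor trait — the same
#' rank-quantile rule as [derive_categorical_trait()] — so regression and
#' classification models can be compared with the same accuracy metric.
#'
#' @param yhat predicted continuous values.
#' @param class_proportions observed class proportions (positive, summing
#'   to 1), lowest-value class first. A named vector or the `labels`
#'   argument carries the class labels.
#' @param labels optional class labels; defaults to
#'   `names(class_proportions)` or `cat1..catK`.
#' @return An ordered factor of mapped class labels.
#' @export
map_regression_to_categories <- function(yhat, class_proportions, labels = NULL) {
  if (is.null(labels)) labels <- names(class_proportions)
  derive_categorical_trait(yhat, unname(class_proportions), labels = labels)
}

#' Paired comparison of two cross-validated metric series
#'
#' Two-sided paired t-test on per-cross-validation-set differences, the
#' comparison used to contrast models (e.g. single- vs multi-trait) over
#' the same 150 CV sets. With identical series the statistic is 0 and the
#' p-value 1; a zero-variance non-zero difference is degenerate and is
#' reported with `p = 0` and an infinite statistic.
#'
#' @param metric_a,metric_b equal-length numeric vectors paired by CV set;
#'   `NA` pairs are dropped.
#' @return A list with `t`, `p_value`, `mean_diff`, `n`.
#' @export
paired_cv_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  ok <- !is.na(metric_a) & !is.na(metric_b)
  a <- metric_a[ok]; b <- metric_b[ok]
  d <- a - b
  if (length(d) < 2) stop("need at least 2 paired values")
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (all(d == 0)) return(list(t = 0, p_value = 1, mean_diff = 0, n = length(d)))
    warning("zero-variance non-zero differences: degenerate paired t-test")
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_diff = mean(d),
                n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d))
}
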
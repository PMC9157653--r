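#' Classifier specification for ordinal descriptor traits
#'
#' Two families are supported, mirroring the usual choices for categorical
#' genomic prediction: `tree_ensemble` (bootstrap-aggregated decision trees
#' with 1000 trees and `floor(sqrt(p))` split candidates per node) and
#' `kernel_margin` (radial-basis-kernel maximum-margin classification with
#' cost and kernel-width each tuned over a 15-value grid by inner
#' cross-validated accuracy).
#'
#' The 15 cost values default to log-spaced points on \[1e-2, 1e3\]; the 15
#' kernel-width (gamma) values are log-spaced over four decades around the
#' median heuristic `1 / median(pairwise squared distance)`, resolved at
#' fit time.
#'
#' @param family `"tree_ensemble"` or `"kernel_margin"`.
#' @param n_trees number of trees (tree ensemble).
#' @param split_candidates per-split candidate features; default
#'   `floor(sqrt(p))` at fit time.
#' @param cost_grid 15 positive cost values (kernel margin).
#' @param width_grid optional 15 positive gamma values; `NULL` for the
#'   median heuristic.
#' @param inner_cv_folds folds of the inner tuning cross-validation.
#' @param seed integer seed; fits are deterministic given it.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("tree_ensemble", "kernel_margin"),
                            n_trees = 1000, split_candidates = NULL,
                            cost_grid = 10^seq(-2, 3, length.out = 15),
                            width_grid = NULL,
                            inner_cv_folds = 5, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_trees >= 1, length(cost_grid) == 15, all(cost_grid > 0),
            inner_cv_folds >= 2)
  if (!is.null(width_grid)) stopifnot(length(width_grid) == 15, all(width_grid > 0))
  structure(list(family = family, n_trees = as.integer(n_trees),
                 split_candidates = split_candidates,
                 cost_grid = cost_grid, width_grid = width_grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances class counts by interpolation: for each synthetic sample a
#' minority observation `x` and one of its `k` nearest same-class
#' neighbours `z` (Euclidean distance) are chosen, and `x + U(0,1) (z - x)`
#' is emitted, so synthetic points lie on segments between same-class
#' neighbours. Every class is oversampled up to the majority count.
#' Singleton classes cannot be interpolated and are duplicated with a
#' warning. Deterministic under `seed`.
#'
#' @param Xf samples x features numeric matrix.
#' @param labels factor (or coercible) of class labels, length `nrow(Xf)`.
#' @param k number of nearest neighbours considered (default 5, capped at
#'   class size minus one).
#' @param seed integer seed.
#' @return A list with `Xf` (original rows then synthetic rows) and
#'   `labels`.
#' @export
smote <- function(Xf, labels, k = 5, seed = 1L) {
  Xf <- as.matrix(Xf)
  labels <- factor(labels)
  stopifnot(nrow(Xf) == length(labels), k >= 1)
  set.seed(seed)
  counts <- table(labels)
  target <- max(counts)
  new_x <- list(); new_lab <- character(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    idx <- which(labels == cl)
    if (length(idx) == 1L) {
      warning("class '", cl, "' has a single sample; duplicating instead of interpolating")
      new_x[[cl]] <- Xf[rep(idx, need), , drop = FALSE]
      new_lab <- c(new_lab, rep(cl, need))
      next
    }
    Xc <- Xf[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    kk <- min(k, length(idx) - 1L)
    nn <- apply(D, 1, function(r) order(r)[seq_len(kk)])
    nn <- matrix(nn, nrow = kk)
    base <- sample.int(length(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(kk, 1L), b], integer(1))
    u <- stats::runif(need)
    new_x[[cl]] <- Xc[base, , drop = FALSE] +
      u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    new_lab <- c(new_lab, rep(cl, need))
  }
  if (length(new_lab) == 0) return(list(Xf = Xf, labels = labels))
  out_x <- rbind(Xf, do.call(rbind, new_x))
  rownames(out_x) <- NULL
  list(Xf = out_x, labels = factor(c(as.character(labels), new_lab),
                                   levels = levels(labels)))
}

#' Fit a classification-based genomic prediction model
#'
#' Trains the family requested in `spec` on a samples x features matrix
#' (typically a tag-SNP dosage matrix) and class labels. The kernel-margin
#' family selects `(cost, gamma)` from the 15 x 15 grid by inner
#' cross-validated accuracy (ties go to the first grid point in row-major
#' order) before the final fit on all training data.
#'
#' @param spec a [classifier_spec()].
#' @param Xf samples x features matrix.
#' @param labels class labels (factor or coercible); at least 2 classes.
#' @return An object of class `gs_classifier` wrapping the fitted learner,
#'   with `family`, `levels`, `feature_names` and (for kernel margin) the
#'   selected `cost`/`gamma`.
#' @export
fit_classifier <- function(spec, Xf, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  Xf <- as.matrix(Xf)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("training labels contain a single class")
  if (is.null(colnames(Xf))) colnames(Xf) <- sprintf("F%05d", seq_len(ncol(Xf)))
  set.seed(spec$seed)
  if (spec$family == "tree_ensemble") {
    mtry <- spec$split_candidates %||% max(1L, floor(sqrt(ncol(Xf))))
    fit <- randomForest::randomForest(x = Xf, y = labels,
                                      ntree = spec$n_trees, mtry = mtry)
    tuned <- NULL
  } else {
    width_grid <- spec$width_grid
    if (is.null(width_grid)) {
      d2 <- stats::dist(Xf[sample.int(nrow(Xf), min(200L, nrow(Xf))), , drop = FALSE])^2
      g0 <- 1 / max(stats::median(d2), .Machine$double.eps)
      width_grid <- g0 * 10^seq(-2, 2, length.out = 15)
    }
    grid <- expand.grid(cost = spec$cost_grid, gamma = width_grid,
                        KEEP.OUT.ATTRS = FALSE)
    folds <- rep_len(seq_len(spec$inner_cv_folds), nrow(Xf))[sample.int(nrow(Xf))]
    acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      hits <- 0L; tot <- 0L
      for (f in seq_len(spec$inner_cv_folds)) {
        tr <- folds != f
        if (nlevels(droplevels(labels[tr])) < 2) next
        m <- e1071::svm(x = Xf[tr, , drop = FALSE], y = droplevels(labels[tr]),
                        kernel = "radial", cost = grid$cost[gi],
                        gamma = grid$gamma[gi], scale = FALSE)
        p <- stats::predict(m, Xf[!tr, , drop = FALSE])
        hits <- hits + sum(as.character(p) == as.character(labels[!tr]))
        tot <- tot + sum(!tr)
      }
      acc[gi] <- if (tot > 0) hits / tot else 0
    }
    best <- which.max(acc)
    fit <- e1071::svm(x = Xf, y = labels, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE, probability = TRUE)
    tuned <- list(cost = grid$cost[best], gamma = grid$gamma[best],
                  inner_accuracy = acc[best])
  }
  structure(list(family = spec$family, fit = fit, levels = levels(labels),
                 feature_names = colnames(Xf), tuned = tuned, seed = spec$seed),
            class = "gs_classifier")
}

#' Predicted class labels / per-class scores
#'
#' Scores are row-stochastic: tree-vote fractions for the tree ensemble,
#' calibrated class probabilities for the kernel-margin family. Predicted
#' labels are the per-row argmax of the scores.
#'
#' @param fitted a [fit_classifier()] result.
#' @param Xf_new samples x features matrix with the training feature
#'   columns.
#' @return `predict_scores()`: samples x classes matrix with rows summing
#'   to 1; `predict_class()`: factor of labels.
#' @export
predict_scores <- function(fitted, Xf_new) {
  stopifnot(inherits(fitted, "gs_classifier"))
  Xf_new <- as.matrix(Xf_new)
  if (ncol(Xf_new) != length(fitted$feature_names) ||
      (!is.null(colnames(Xf_new)) &&
       !identical(colnames(Xf_new), fitted$feature_names)))
    stop("feature columns do not match the training features")
  colnames(Xf_new) <- fitted$feature_names
  if (fitted$family == "tree_ensemble") {
    sc <- stats::predict(fitted$fit, Xf_new, type = "prob")
  } else {
    p <- stats::predict(fitted$fit, Xf_new, probability = TRUE)
    sc <- attr(p, "probabilities")
    sc <- sc[, fitted$levels, drop = FALSE]
  }
  sc <- sc / pmax(rowSums(sc), .Machine$double.eps)
  unname_rows(sc)
}

#' @rdname predict_scores
#' @export
predict_class <- function(fitted, Xf_new) {
  sc <- predict_scores(fitted, Xf_new)
  factor(fitted$levels[max.col(sc, ties.method = "first")],
         levels = fitted$levels)
}

unname_rows <- function(M) { rownames(M) <- NULL; M }

#' @export
print.gs_classifier <- function(x, ...) {
  cat(sprintf("<gs_classifier> %s over %d features, %d classes",
              x$family, length(x$feature_names), length(x$levels)))
  if (!is.null(x$tuned))
    cat(sprintf(" (cost=%.3g gamma=%.3g, inner accuracy %.3f)",
                x$tuned$cost, x$tuned$gamma, x$tuned$inner_accuracy))
  cat("\n")
  invisible(x)
}
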
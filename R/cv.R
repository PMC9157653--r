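#' Repeated k-fold cross-validation scheme
#'
#' Accessions are split into `n_folds` random folds of (near-)equal size —
#' sizes differ by at most one — independently in each of `n_repetitions`
#' repetitions; every accession is tested exactly once per repetition. The
#' default 5 folds x 30 repetitions gives the study's 150 cross-validation
#' sets. Deterministic under `seed`.
#'
#' @param accession_ids character vector of accession ids.
#' @param n_folds folds per repetition (default 5).
#' @param n_repetitions repetitions (default 30).
#' @param seed integer seed.
#' @return An object of class `cv_scheme`: a tibble `assignments`
#'   (`repetition`, `accession_id`, `fold`) plus the scheme parameters.
#' @export
make_cv_folds <- function(accession_ids, n_folds = 5, n_repetitions = 30,
                          seed = 1L) {
  n <- length(accession_ids)
  stopifnot(n >= n_folds, n_folds >= 2, n_repetitions >= 1)
  set.seed(seed)
  asg <- purrr::map_dfr(seq_len(n_repetitions), function(r) {
    fold <- integer(n)
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    tibble::tibble(repetition = r, accession_id = accession_ids, fold = fold)
  })
  structure(list(assignments = asg, n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %d folds x %d repetitions = %d CV sets over %d accessions (seed %d)\n",
              x$n_folds, x$n_repetitions, x$n_folds * x$n_repetitions,
              length(unique(x$assignments$accession_id)), x$seed))
  invisible(x)
}

#' Run repeated cross-validation of a genomic prediction model
#'
#' For every (repetition, fold) set the model is fitted on the training
#' folds only — marker centring, REML, SMOTE and hyperparameter tuning all
#' happen inside the training data — and evaluated on the held-out fold.
#' Regression models report Pearson and Spearman correlations and the
#' top-30%/top-15% matched rates; classification models report accuracy
#' and (macro one-vs-rest) AUC. Folds where a metric is undefined (e.g. a
#' constant prediction, or a single-class test fold for AUC) record `NA`
#' and are excluded from summaries.
#'
#' @param G a complete [geno_matrix()].
#' @param response for `model = "rrblup"`, a named numeric vector of
#'   genetic values; for `"multitrait"`, an accessions x traits matrix with
#'   row names; for `"classifier"`, a named factor of class labels. Names
#'   must cover `G`'s accessions.
#' @param model `"rrblup"`, `"multitrait"` or `"classifier"`.
#' @param scheme a [make_cv_folds()] scheme over the same accessions.
#' @param markers optional variant ids used as predictors (e.g. a
#'   [tag_subset()]); default all.
#' @param lambda optional fixed ridge ratio passed to [fit_rrblup()].
#' @param classifier a [classifier_spec()] (required for
#'   `model = "classifier"`).
#' @param use_smote apply [smote()] inside each training fold
#'   (classification only).
#' @param class_proportions optional class proportions: when supplied with
#'   a regression model, predictions are additionally mapped onto
#'   categories by [map_regression_to_categories()] and an `accuracy`
#'   metric row is emitted per set (the regression-vs-classification
#'   comparison).
#' @param class_labels optional named factor of observed descriptor labels;
#'   when given, the mapped predictions are scored against these labels
#'   (the paper-style comparison). Otherwise the observed continuous
#'   response is quantile-mapped with the same rule and used as truth.
#' @return A `cv_report`: tibble with columns `repetition`, `fold`,
#'   `trait`, `metric`, `value` (one row per CV set, metric and trait) and
#'   attributes `model` and `n_sets`.
#' @export
run_cv <- function(G, response, model = c("rrblup", "multitrait", "classifier"),
                   scheme, markers = NULL, lambda = NULL, classifier = NULL,
                   use_smote = TRUE, class_proportions = NULL,
                   class_labels = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(G, "geno_matrix"), inherits(scheme, "cv_scheme"))
  check_complete(G, "cross-validation")
  acc <- G$meta$accession_id
  Z <- G$dosage
  if (!is.null(markers)) {
    j <- match(markers, G$map$variant_id)
    if (anyNA(j)) stop("unknown marker id in `markers`")
    Z <- Z[, j, drop = FALSE]
  }
  if (model == "multitrait") {
    Y <- as.matrix(response)
    if (is.null(rownames(Y))) stop("multitrait response needs row names")
    if (!all(acc %in% rownames(Y))) stop("response does not cover all accessions")
    Y <- Y[acc, , drop = FALSE]
  } else {
    if (is.null(names(response))) stop("response must be named by accession id")
    if (!all(acc %in% names(response))) stop("response does not cover all accessions")
    response <- response[acc]
  }
  if (model == "classifier" && is.null(classifier))
    stop("supply a classifier_spec() for model = 'classifier'")

  sets <- dplyr::distinct(scheme$assignments[, c("repetition", "fold")])
  out <- vector("list", nrow(sets))
  n_skipped <- 0L
  for (s in seq_len(nrow(sets))) {
    rp <- sets$repetition[s]; fl <- sets$fold[s]
    test_ids <- scheme$assignments$accession_id[
      scheme$assignments$repetition == rp & scheme$assignments$fold == fl]
    te <- match(test_ids, acc)
    tr <- setdiff(seq_along(acc), te)
    res <- cv_fit_one(Z, response, model, tr, te, lambda, classifier,
                      use_smote, class_proportions, class_labels,
                      seed = scheme$seed * 1000L + s)
    if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
    res$repetition <- rp; res$fold <- fl
    out[[s]] <- res
  }
  if (n_skipped > 0)
    message(n_skipped, " CV set(s) skipped (single-class training fold)")
  rep_tbl <- dplyr::bind_rows(out)[, c("repetition", "fold", "trait",
                                       "metric", "value")]
  structure(rep_tbl, class = c("cv_report", class(rep_tbl)),
            model = model, n_sets = nrow(sets) - n_skipped)
}

# internal: fit/evaluate one train/test split; returns long tibble or NULL
cv_fit_one <- function(Z, response, model, tr, te, lambda, classifier,
                       use_smote, class_proportions, class_labels, seed) {
  if (model == "rrblup") {
    fit <- fit_rrblup(Z[tr, , drop = FALSE], response[tr], lambda = lambda)
    yhat <- predict(fit, Z[te, , drop = FALSE])
    y <- response[te]
    res <- tibble::tibble(trait = "trait",
                          metric = c("pearson", "spearman", "top30_match",
                                     "top15_match"),
                          value = c(metric_pearson(yhat, y),
                                    metric_spearman(yhat, y),
                                    metric_top_match(yhat, y, 0.30),
                                    metric_top_match(yhat, y, 0.15)))
    if (!is.null(class_proportions)) {
      mapped <- map_regression_to_categories(yhat, class_proportions)
      truecl <- if (!is.null(class_labels)) class_labels[names(y)] else
        map_regression_to_categories(y, class_proportions)
      res <- dplyr::bind_rows(res, tibble::tibble(
        trait = "trait", metric = "accuracy",
        value = metric_accuracy(mapped, truecl)))
    }
    return(res)
  }
  if (model == "multitrait") {
    ctr <- colMeans(Z[tr, , drop = FALSE])
    Ktr <- kinship(Z[tr, , drop = FALSE], center = ctr)
    Kcr <- tcrossprod(sweep(Z[te, , drop = FALSE], 2, ctr),
                      sweep(Z[tr, , drop = FALSE], 2, ctr)) / ncol(Z)
    fit <- fit_multitrait(Ktr, response[tr, , drop = FALSE])
    pred <- predict(fit, Kcr)
    Yte <- response[te, , drop = FALSE]
    res <- purrr::map_dfr(seq_len(ncol(Yte)), function(k) {
      tibble::tibble(trait = colnames(Yte)[k],
                     metric = c("pearson", "spearman", "top30_match",
                                "top15_match"),
                     value = c(metric_pearson(pred[, k], Yte[, k]),
                               metric_spearman(pred[, k], Yte[, k]),
                               metric_top_match(pred[, k], Yte[, k], 0.30),
                               metric_top_match(pred[, k], Yte[, k], 0.15)))
    })
    rv <- tryCatch(rv_coefficient(pred, Yte), error = function(e) NA_real_)
    return(dplyr::bind_rows(res, tibble::tibble(trait = "(all)", metric = "rv",
                                                value = rv)))
  }
  # classification
  lab_tr <- droplevels(factor(response[tr]))
  if (nlevels(lab_tr) < 2) return(NULL)
  Xtr <- Z[tr, , drop = FALSE]
  if (use_smote) {
    bal <- smote(Xtr, lab_tr, seed = seed)
    Xtr <- bal$Xf; lab_tr <- bal$labels
  }
  spec <- classifier
  spec$seed <- seed
  fit <- fit_classifier(spec, Xtr, lab_tr)
  sc <- predict_scores(fit, Z[te, , drop = FALSE])
  colnames(sc) <- fit$levels
  pl <- predict_class(fit, Z[te, , drop = FALSE])
  truth <- as.character(response[te])
  auc <- tryCatch(metric_auc(sc, truth), error = function(e) NA_real_)
  tibble::tibble(trait = "trait", metric = c("accuracy", "auc"),
                 value = c(metric_accuracy(pl, truth), auc))
}

#' Summarise a cross-validation report
#'
#' Mean and standard deviation of each metric over CV sets (undefined sets
#' excluded), the "mean values and standard deviations" presentation of
#' predictability.
#'
#' @param report a [run_cv()] report.
#' @return A tibble (`trait`, `metric`, `mean`, `sd`, `n_sets`, `n_missing`).
#' @export
summarise_cv <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(report), .data$trait,
                                   .data$metric),
                   mean = mean(.data$value, na.rm = TRUE),
                   sd = stats::sd(.data$value, na.rm = TRUE),
                   n_sets = sum(!is.na(.data$value)),
                   n_missing = sum(is.na(.data$value)),
                   .groups = "drop")
}

#' Training/testing splits for population-transfer scenarios
#'
#' Builds the train/test splits used to probe model transfer from the
#' cultivated core to wild accessions:
#' \describe{
#'   \item{`baseline_transfer`}{one split: train on all cultivated, test on
#'     all wild accessions.}
#'   \item{`wild_augment`}{per draw, `n_wild` wild accessions are sampled
#'     (with at least one per wild species when `stratify_species`), the
#'     training set is all cultivated plus the sample, and the test set the
#'     remaining wild accessions. The study grid is
#'     `n_wild` in \{7, 10, 15, 20, 25, 30\}.}
#'   \item{`wild_balanced`}{per draw, `n_wild` cultivated and `n_wild` wild
#'     accessions train; all remaining accessions test. Study grid
#'     \{7, 10, 15, 20, 25, 30, 34\}.}
#' }
#' Draws are independent and seeded; the default 150 draws mirrors the
#' size of the repeated-CV design.
#'
#' @param meta accession metadata tibble (`accession_id`, `species`,
#'   `is_wild`).
#' @param mode scenario mode (see above).
#' @param n_wild wild accessions in training (augment/balanced modes).
#' @param n_draws number of independent draws (default 150).
#' @param stratify_species require one accession per wild species in each
#'   training draw (augment mode; default `TRUE`).
#' @param seed integer seed.
#' @return A list of `n_draws` (or 1) elements, each
#'   `list(train = ids, test = ids)`.
#' @export
build_scenarios <- function(meta, mode = c("baseline_transfer", "wild_augment",
                                           "wild_balanced"),
                            n_wild = NULL, n_draws = 150,
                            stratify_species = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("accession_id", "species", "is_wild") %in% names(meta)))
  cult <- meta$accession_id[!meta$is_wild]
  wild <- meta$accession_id[meta$is_wild]
  if (length(wild) == 0) stop("no wild accessions in metadata")
  if (mode == "baseline_transfer")
    return(list(list(train = cult, test = wild)))
  stopifnot(!is.null(n_wild), n_wild >= 1, n_wild < length(wild))
  wild_species <- split(wild, meta$species[meta$is_wild])
  if (mode == "wild_augment" && stratify_species &&
      n_wild < length(wild_species))
    stop("n_wild is smaller than the number of wild species; cannot guarantee one accession per species")
  set.seed(seed)
  lapply(seq_len(n_draws), function(dr) {
    if (mode == "wild_augment") {
      pick <- if (stratify_species) {
        base <- vapply(wild_species, function(w) w[sample.int(length(w), 1L)], "")
        extra <- sample(setdiff(wild, base), n_wild - length(base))
        c(base, extra)
      } else sample(wild, n_wild)
      list(train = c(cult, unname(pick)), test = setdiff(wild, pick))
    } else {
      stopifnot(n_wild <= length(cult))
      tr <- c(sample(cult, n_wild), sample(wild, n_wild))
      list(train = tr, test = setdiff(meta$accession_id, tr))
    }
  })
}

#' Evaluate rrBLUP predictability over scenario splits
#'
#' Fits [fit_rrblup()] on each scenario's training accessions and scores
#' the Pearson predictability on its test accessions.
#'
#' @param G a complete [geno_matrix()].
#' @param y named numeric response covering all accessions.
#' @param scenarios a [build_scenarios()] list.
#' @param markers optional predictor variant ids.
#' @param lambda optional fixed ridge ratio.
#' @return A tibble (`draw`, `n_train`, `n_test`, `pearson`).
#' @export
run_scenarios <- function(G, y, scenarios, markers = NULL, lambda = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  check_complete(G, "scenario evaluation")
  Z <- G$dosage
  if (!is.null(markers)) Z <- Z[, match(markers, G$map$variant_id), drop = FALSE]
  purrr::map_dfr(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    tr <- match(sc$train, rownames(Z)); te <- match(sc$test, rownames(Z))
    fit <- fit_rrblup(Z[tr, , drop = FALSE], y[sc$train], lambda = lambda)
    yhat <- predict(fit, Z[te, , drop = FALSE])
    tibble::tibble(draw = i, n_train = length(tr), n_test = length(te),
                   pearson = metric_pearson(yhat, y[sc$test]))
  })
}
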
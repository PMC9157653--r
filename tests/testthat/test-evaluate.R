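test_that("CV folds partition accessions evenly and are seed-deterministic", {
  ids <- sprintf("a%02d", 1:10)
  sch <- make_cv_folds(ids, n_folds = 5, n_repetitions = 30, seed = 3)
  sizes <- dplyr::count(sch$assignments, .data$repetition, .data$fold)
  expect_true(all(sizes$n == 2))
  # every accession tested exactly once per repetition = 30 times in total
  per_acc <- dplyr::count(sch$assignments, .data$accession_id)
  expect_true(all(per_acc$n == 30))
  sch2 <- make_cv_folds(ids, n_folds = 5, n_repetitions = 30, seed = 3)
  expect_identical(sch$assignments, sch2$assignments)
  # n not divisible by k: fold sizes differ by at most one
  sch3 <- make_cv_folds(sprintf("b%02d", 1:13), n_folds = 5,
                        n_repetitions = 2, seed = 4)
  sizes3 <- dplyr::count(sch3$assignments, .data$repetition, .data$fold)
  expect_lte(max(sizes3$n) - min(sizes3$n), 1)
})

test_that("perfect linear signal gives near-unit CV predictability, null gives none", {
  # fewer markers than training accessions, so the no-noise single-marker
  # function is exactly identifiable
  G <- cached("perfect100", simulate_genotypes(population_spec(
    n_cultivated = 100, wild_group_sizes = integer(0), n_snps = 50,
    n_chromosomes = 2, ld_rho = 0, missing_rate = 0, seed = 20)))
  # y a fixed linear function of one marker, no noise
  y <- stats::setNames(2 * G$dosage[, 7] + 1, G$meta$accession_id)
  sch <- make_cv_folds(G$meta$accession_id, n_repetitions = 2, seed = 5)
  rep_perfect <- run_cv(G, y, "rrblup", sch)
  expect_gte(mean(dplyr::filter(tibble::as_tibble(rep_perfect),
                                .data$metric == "pearson")$value), 0.99)
  expect_equal(nrow(dplyr::distinct(tibble::as_tibble(rep_perfect),
                                    .data$repetition, .data$fold)), 10)
  # y independent of genotype: averaged over noise draws because the CV
  # sets reuse one response and are therefore strongly dependent
  G3 <- cached("null300", simulate_genotypes(population_spec(
    n_cultivated = 300, wild_group_sizes = integer(0), n_snps = 400,
    missing_rate = 0, seed = 22)))
  sch3 <- make_cv_folds(G3$meta$accession_id, n_repetitions = 1, seed = 5)
  m0 <- mean(vapply(1:3, function(s) {
    set.seed(6 + s)
    y0 <- stats::setNames(stats::rnorm(300), G3$meta$accession_id)
    rep_null <- suppressWarnings(run_cv(G3, y0, "rrblup", sch3))
    mean(dplyr::filter(tibble::as_tibble(rep_null),
                       .data$metric == "pearson")$value, na.rm = TRUE)
  }, numeric(1)))
  expect_gt(m0, -0.1); expect_lt(m0, 0.1)
})

test_that("a full scheme produces one record set per CV set", {
  G <- small_panel()
  set.seed(7)
  y <- stats::setNames(stats::rnorm(100), G$meta$accession_id)
  sch <- make_cv_folds(G$meta$accession_id, n_folds = 5, n_repetitions = 3,
                       seed = 8)
  rep1 <- suppressWarnings(run_cv(G, y, "rrblup", sch))
  tab <- tibble::as_tibble(rep1)
  expect_equal(nrow(dplyr::distinct(tab, .data$repetition, .data$fold)), 15)
  expect_setequal(unique(tab$metric),
                  c("pearson", "spearman", "top30_match", "top15_match"))
  s <- summarise_cv(rep1)
  expect_true(all(c("mean", "sd", "n_sets") %in% names(s)))
})

test_that("no test-fold information reaches training", {
  # perturbing a test accession's phenotype must not change its prediction:
  # refit with one accession's y changed and compare that accession's
  # predicted value in every set where it is in the test fold
  G <- small_panel()
  st <- simulate_trait(G, trait_spec(n_qtl = 40, h2 = 0.6, seed = 9))
  y <- st$truth[G$meta$accession_id]
  sch <- make_cv_folds(G$meta$accession_id, n_repetitions = 1, seed = 10)
  target <- G$meta$accession_id[1]
  fold_of_target <- sch$assignments$fold[sch$assignments$accession_id == target]
  pred_for <- function(yy) {
    te_ids <- sch$assignments$accession_id[sch$assignments$fold == fold_of_target]
    tr_ids <- setdiff(G$meta$accession_id, te_ids)
    fit <- fit_rrblup(G$dosage[tr_ids, ], yy[tr_ids])
    predict(fit, G$dosage[te_ids, , drop = FALSE])[te_ids == target]
  }
  y2 <- y; y2[target] <- y2[target] + 100
  expect_identical(pred_for(y), pred_for(y2))
})

test_that("metrics hit their closed-form values on constructed cases", {
  y <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10)
  expect_equal(metric_pearson(y, y), 1)
  expect_equal(metric_pearson(-y, y), -1)
  expect_equal(metric_pearson(2 * y + 3, y), 1)
  expect_true(is.na(metric_pearson(rep(1, 10), y)))
  expect_equal(metric_spearman(exp(y), y), 1)  # rank invariance
  expect_equal(metric_top_match(y, y, 0.3), 1)
  expect_equal(metric_top_match(-y, y, 0.3), 0)
  # engineered overlap of 2 in the top 3
  yhat <- c(0, 0, 10, 0, 9, 0, 0, 0, 8, 0)  # top-3: positions 3, 5, 9
  # top-3 of y: positions 10, 5, 3 -> overlap {3, 5} = 2
  expect_equal(metric_top_match(yhat, y, 0.3), 2 / 3)
  expect_equal(metric_accuracy(c("A", "A", "B"), c("A", "B", "B")), 2 / 3)
  expect_equal(metric_accuracy(c("A", "B"), c("A", "B")), 1)
  expect_equal(metric_accuracy(c("B", "A"), c("A", "B")), 0)
})

test_that("AUC behaves as a rank statistic with macro-averaged multiclass", {
  # perfectly separating scores
  truth <- rep(c("neg", "pos"), each = 20)
  sc <- cbind(neg = c(stats::runif(20, 0.6, 1), stats::runif(20, 0, 0.4)),
              pos = c(stats::runif(20, 0, 0.4), stats::runif(20, 0.6, 1)))
  expect_equal(metric_auc(sc, truth), 1)
  # monotone transform invariance
  expect_equal(metric_auc(cbind(neg = sc[, 1], pos = exp(3 * sc[, 2])), truth), 1)
  # null scores: AUC ~ 0.5 at n = 500
  set.seed(11)
  truth0 <- sample(c("a", "b"), 500, replace = TRUE)
  sc0 <- matrix(stats::runif(1000), 500, dimnames = list(NULL, c("a", "b")))
  expect_lt(abs(metric_auc(sc0, truth0) - 0.5), 0.05)
  # multiclass macro one-vs-rest stays within [0, 1] and rejects degenerate truth
  truth3 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  sc3 <- matrix(stats::runif(180), 60, dimnames = list(NULL, c("a", "b", "c")))
  expect_gte(metric_auc(sc3, truth3), 0)
  expect_lte(metric_auc(sc3, truth3), 1)
  expect_error(metric_auc(sc0, rep("a", 500)), "single class")
})

test_that("regression predictions map onto categories by observed quantiles", {
  yhat <- stats::rnorm(10)
  mapped <- map_regression_to_categories(yhat, c(0.2, 0.2, 0.6))
  expect_equal(as.integer(table(mapped)), c(2L, 2L, 6L))
  # monotone transform of yhat leaves labels unchanged
  expect_identical(map_regression_to_categories(2 * yhat + 1, c(0.2, 0.2, 0.6)),
                   mapped)
  # perfectly ordered predictions give accuracy 1 against the same-rule truth
  y <- sort(stats::rnorm(10))
  truecl <- derive_categorical_trait(y, c(0.5, 0.5))
  expect_equal(metric_accuracy(
    map_regression_to_categories(rank(y), c(0.5, 0.5)), truecl), 1)
})

test_that("scenario builders respect stratification, disjointness and seeding", {
  G <- structured_panel()
  base <- build_scenarios(G$meta, "baseline_transfer")
  expect_length(base, 1)
  expect_setequal(base[[1]]$train, G$meta$accession_id[!G$meta$is_wild])
  expect_setequal(base[[1]]$test, G$meta$accession_id[G$meta$is_wild])
  aug <- build_scenarios(G$meta, "wild_augment", n_wild = 7, n_draws = 25,
                         seed = 12)
  sp_of <- stats::setNames(G$meta$species, G$meta$accession_id)
  for (d in aug) {
    expect_length(intersect(d$train, d$test), 0)
    expect_setequal(c(d$train, d$test), G$meta$accession_id)
    wild_tr <- d$train[startsWith(sp_of[d$train], "wild")]
    expect_length(wild_tr, 7)
    # pigeonhole: exactly one accession per wild species
    expect_equal(sort(unname(table(sp_of[wild_tr]))), rep(1L, 7),
                 ignore_attr = TRUE)
  }
  expect_error(build_scenarios(G$meta, "wild_augment", n_wild = 5, seed = 1),
               "smaller than the number of wild species")
  bal <- build_scenarios(G$meta, "wild_balanced", n_wild = 10, n_draws = 5,
                         seed = 13)
  for (d in bal) {
    expect_equal(sum(startsWith(sp_of[d$train], "wild")), 10)
    expect_equal(sum(!startsWith(sp_of[d$train], "wild")), 10)
    expect_length(intersect(d$train, d$test), 0)
  }
  expect_identical(build_scenarios(G$meta, "wild_augment", n_wild = 7,
                                   n_draws = 5, seed = 14),
                   build_scenarios(G$meta, "wild_augment", n_wild = 7,
                                   n_draws = 5, seed = 14))
})

test_that("paired CV comparison behaves at its limits and under swapping", {
  a <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  expect_equal(paired_cv_test(a, a), list(t = 0, p_value = 1, mean_diff = 0,
                                          n = 5))
  set.seed(15)
  b <- a + 0.2 + stats::rnorm(5, sd = 0.01)
  r1 <- paired_cv_test(b, a)
  expect_lt(r1$p_value, 1e-4)
  r2 <- paired_cv_test(a, b)
  expect_equal(r2$t, -r1$t, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  expect_warning(r3 <- paired_cv_test(a + 1, a), "degenerate")
  expect_equal(r3$p_value, 0)
})

test_that("classification CV reports accuracy and AUC per set with SMOTE inside folds", {
  G <- small_panel()
  st <- simulate_trait(G, trait_spec(n_qtl = 10, h2 = 0.9, n_trials = 1,
                                     n_reps = 1, trial_var_frac = 0, seed = 16))
  labels <- derive_categorical_trait(st$truth[G$meta$accession_id],
                                     c(0.7, 0.3))
  names(labels) <- G$meta$accession_id
  sch <- make_cv_folds(G$meta$accession_id, n_repetitions = 1, seed = 17)
  rep1 <- run_cv(G, labels, "classifier", sch,
                 classifier = classifier_spec("tree_ensemble", n_trees = 150),
                 use_smote = TRUE)
  tab <- tibble::as_tibble(rep1)
  expect_setequal(unique(tab$metric), c("accuracy", "auc"))
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$value >= 0 & tab$value <= 1, na.rm = TRUE))
})

test_that("cv_report autoplot and tidiers produce the expected structures", {
  G <- small_panel()
  set.seed(18)
  y <- stats::setNames(stats::rnorm(100), G$meta$accession_id)
  sch <- make_cv_folds(G$meta$accession_id, n_repetitions = 1, seed = 19)
  rep1 <- suppressWarnings(run_cv(G, y, "rrblup", sch))
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_s3_class(glance(rep1), "tbl_df")
  p <- ggplot2::ggplot_build(autoplot(rep1))
  expect_s3_class(p$plot, "ggplot")
})
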
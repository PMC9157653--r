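#' Specification of simulated polygenic traits
#'
#' Controls the genetic architecture and trial/replicate structure of traits
#' generated by [simulate_trait()] and [simulate_multitrait()]. The
#' single-observation phenotypic variance is normalised to 1, with a fraction
#' `h2` genetic and the remaining `1 - h2` split between trial effects
#' (`trial_var_frac`) and replicate-level residuals.
#'
#' @param n_qtl number of causal SNPs (sampled uniformly from the panel).
#' @param h2 target narrow-sense heritability of a single observation, in
#'   \[0, 1\].
#' @param n_trials number of trials (default 4, a tomato-style design; use 3
#'   for a pepper-style design).
#' @param trial_var_frac fraction of the non-genetic variance assigned to
#'   trial main effects, in \[0, 1\].
#' @param n_reps replicates (sampled fruits) per accession and trial.
#' @param genetic_corr optional t x t genetic correlation matrix for
#'   multi-trait simulation: symmetric positive semi-definite, unit diagonal.
#' @param mu grand mean added to every observation.
#' @param seed integer RNG seed.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(n_qtl = 100, h2 = 0.6, n_trials = 4,
                       trial_var_frac = 0.3, n_reps = 8,
                       genetic_corr = NULL, mu = 0, seed = 1L) {
  stopifnot(n_qtl >= 1, h2 >= 0, h2 <= 1, n_trials >= 1,
            trial_var_frac >= 0, trial_var_frac <= 1, n_reps >= 1)
  if (!is.null(genetic_corr)) {
    genetic_corr <- as.matrix(genetic_corr)
    if (!isSymmetric(unname(genetic_corr), tol = 1e-8))
      stop("genetic_corr must be symmetric")
    if (max(abs(diag(genetic_corr) - 1)) > 1e-8)
      stop("genetic_corr must have unit diagonal")
    if (min(eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("genetic_corr must be positive semi-definite")
  }
  structure(list(n_qtl = as.integer(n_qtl), h2 = h2,
                 n_trials = as.integer(n_trials),
                 trial_var_frac = trial_var_frac, n_reps = as.integer(n_reps),
                 genetic_corr = genetic_corr, mu = mu, seed = as.integer(seed)),
            class = "trait_spec")
}

#' Simulate correlated polygenic traits with trial structure
#'
#' Samples `n_qtl` causal SNPs shared by all traits and per-trait effect
#' vectors whose rows are drawn from N(0, `genetic_corr`), so breeding values
#' reproduce the requested genetic correlations up to sampling error. Each
#' trait's breeding value is rescaled to variance `h2`; trial effects and
#' replicate residuals carry the remaining `1 - h2` (split by
#' `trial_var_frac`), giving unit single-observation variance. Observations
#' follow `value = mu + g_i + t_j + e_ijk`.
#'
#' @param G a complete (no missing calls) [geno_matrix()].
#' @param spec a [trait_spec()] with `genetic_corr` present (t x t).
#' @param trait_names optional character vector of trait names.
#' @return A list with elements `phenotypes` (long tibble: `accession_id`,
#'   `trial`, `rep`, `trait`, `value`), `truth` (accessions x traits matrix
#'   of true breeding values), and `components` (realised variance
#'   decomposition per trait, computed from the generated components before
#'   summation).
#' @export
simulate_multitrait <- function(G, spec, trait_names = NULL) {
  stopifnot(inherits(G, "geno_matrix"), inherits(spec, "trait_spec"))
  check_complete(G, "trait simulation")
  if (is.null(spec$genetic_corr)) stop("spec$genetic_corr must be provided (use trait_spec(genetic_corr = ...))")
  Z <- G$dosage
  n <- nrow(Z); m <- ncol(Z)
  if (spec$n_qtl > m) stop("n_qtl exceeds the number of SNPs")
  t <- nrow(spec$genetic_corr)
  if (is.null(trait_names)) trait_names <- sprintf("trait_%d", seq_len(t))
  stopifnot(length(trait_names) == t)

  set.seed(spec$seed)
  qtl <- sample.int(m, spec$n_qtl)
  # rows of B ~ N(0, genetic_corr): shared causal loci, correlated effects
  ev <- eigen(spec$genetic_corr, symmetric = TRUE)
  corr_sqrt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), t) %*% t(ev$vectors)
  B <- matrix(stats::rnorm(spec$n_qtl * t), ncol = t) %*% corr_sqrt
  Zq <- scale(Z[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  g_raw <- Zq %*% B

  # rescale each trait's breeding values to variance h2 exactly; at h2 = 0
  # the phenotype carries no genetic signal, but the standardised genetic
  # score is still returned as the truth so null-recovery checks (expected
  # correlation ~ 0) stay well-defined
  gv <- matrix(0, n, t, dimnames = list(rownames(Z), trait_names))
  for (k in seq_len(t)) {
    s <- stats::sd(g_raw[, k])
    if (s > 0) gv[, k] <- g_raw[, k] * sqrt(max(spec$h2, .Machine$double.eps)) / s
  }
  gv_pheno <- if (spec$h2 > 0) gv else gv * 0
  if (spec$h2 == 0) gv <- gv / sqrt(.Machine$double.eps)

  var_noise <- 1 - spec$h2
  var_t <- spec$trial_var_frac * var_noise
  var_e <- var_noise - var_t
  trial_ids <- sprintf("trial_%d", seq_len(spec$n_trials))

  recs <- vector("list", t)
  comps <- vector("list", t)
  for (k in seq_len(t)) {
    tr_eff <- if (var_t > 0) stats::rnorm(spec$n_trials, sd = sqrt(var_t)) else numeric(spec$n_trials)
    nobs <- n * spec$n_trials * spec$n_reps
    e <- if (var_e > 0) stats::rnorm(nobs, sd = sqrt(var_e)) else numeric(nobs)
    grid <- expand.grid(accession_id = rownames(Z), trial = trial_ids,
                        rep = seq_len(spec$n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- gv_pheno[grid$accession_id, k]
    tj <- tr_eff[match(grid$trial, trial_ids)]
    recs[[k]] <- tibble::tibble(accession_id = grid$accession_id,
                                trial = grid$trial, rep = grid$rep,
                                trait = trait_names[k],
                                value = spec$mu + gi + tj + e)
    comps[[k]] <- list(var_g = stats::var(gv_pheno[, k]),
                       var_t = if (spec$n_trials > 1) stats::var(tr_eff) else var_t,
                       var_e = stats::var(e))
  }
  names(comps) <- trait_names
  list(phenotypes = dplyr::bind_rows(recs), truth = gv, components = comps,
       qtl_ids = colnames(Z)[qtl])
}

#' Simulate one polygenic trait with trial structure
#'
#' Single-trait convenience wrapper around [simulate_multitrait()] (a 1 x 1
#' genetic correlation matrix); identical seeds give identical data in both.
#'
#' @inheritParams simulate_multitrait
#' @param trait_name name used in the long phenotype table.
#' @return A list with `phenotypes` (long tibble), `truth` (named numeric
#'   vector of true breeding values) and `components`.
#' @export
simulate_trait <- function(G, spec, trait_name = "trait_1") {
  spec$genetic_corr <- matrix(1, 1, 1)
  out <- simulate_multitrait(G, spec, trait_names = trait_name)
  out$truth <- stats::setNames(out$truth[, 1], rownames(out$truth))
  out
}

#' Discretise a continuous value into ordinal categories by rank quantiles
#'
#' Class sizes follow a floor/largest-remainder allocation of
#' `proportions * n`; values are ranked (stable in input order) and the
#' lowest values receive the first class. Tied values always share a class:
#' every member of a tie group gets the lowest class any of them would get
#' by stable rank, so with all values equal every observation lands in the
#' first class, and any strictly increasing transform of `values` yields
#' identical labels.
#'
#' @param values numeric vector (e.g. per-accession genetic values).
#' @param proportions positive class proportions summing to 1, ordered from
#'   the lowest-value class to the highest.
#' @param labels optional class labels (default `cat1`, `cat2`, ...).
#' @return An ordered factor of length `length(values)`.
#' @export
derive_categorical_trait <- function(values, proportions, labels = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1,
            all(proportions > 0), abs(sum(proportions) - 1) < 1e-8)
  k <- length(proportions)
  if (is.null(labels)) labels <- sprintf("cat%d", seq_len(k))
  stopifnot(length(labels) == k)
  n <- length(values)
  counts <- floor(proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- proportions * n - counts
    counts[order(-frac, seq_len(k))[seq_len(rem)]] <- counts[order(-frac, seq_len(k))[seq_len(rem)]] + 1L
  }
  ord <- order(values, seq_len(n))           # stable ascending rank
  tentative <- integer(n)
  tentative[ord] <- rep(seq_len(k), counts)
  cls <- stats::ave(tentative, match(values, values), FUN = min)
  factor(labels[cls], levels = labels, ordered = TRUE)
}
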
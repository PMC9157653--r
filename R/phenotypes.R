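#' Per-trial replicate means
#'
#' Averages replicates within each (accession, trial) cell of a long-format
#' phenotype table. Cells with no observation stay missing (`NA`), never
#' zero, so unbalanced designs flow through to the mixed model unharmed.
#'
#' @param tbl long-format tibble with columns `accession_id`, `trial`,
#'   `rep`, `trait`, `value`.
#' @param trait name of the (continuous) trait to extract.
#' @return An accessions x trials numeric matrix of cell means, accessions
#'   in first-appearance order.
#' @export
trial_means <- function(tbl, trait) {
  stopifnot(all(c("accession_id", "trial", "value", "trait") %in% names(tbl)))
  sub <- dplyr::filter(tbl, .data$trait == !!trait)
  if (nrow(sub) == 0) stop("trait '", trait, "' not present in table")
  acc <- unique(sub$accession_id)
  trials <- unique(sub$trial)
  cell <- dplyr::summarise(dplyr::group_by(sub, .data$accession_id, .data$trial),
                           value = mean(.data$value), .groups = "drop")
  M <- matrix(NA_real_, length(acc), length(trials), dimnames = list(acc, trials))
  M[cbind(match(cell$accession_id, acc), match(cell$trial, trials))] <- cell$value
  M
}

#' Fit the trial-level mixed model and extract genetic values
#'
#' Fits `y_ij = mu + g_i + t_j + e_ij` to the accession x trial cell-mean
#' matrix, with a fixed intercept and independent random genotype and trial
#' effects, by EM-REML on Henderson's mixed-model equations. Variance
#' components are clamped at zero (a small positive floor), iterations run
#' to a relative tolerance of 1e-8 (at most `max_iter`), and the restricted
#' log-likelihood is recorded each iteration (it is non-decreasing under
#' EM). BLUPs of the genotype effects are taken at the converged components;
#' the per-accession genetic value is `mu_hat + BLUP(g)`, the response used
#' downstream by the genomic-prediction models.
#'
#' Missing cells (unbalanced trials) are simply dropped from the response;
#' the mixed-model equations handle the imbalance natively.
#'
#' @param means accessions x trials matrix from [trial_means()], at least
#'   2 x 2.
#' @param trait trait name carried into the summary.
#' @param max_iter maximum EM iterations.
#' @param tol relative convergence tolerance on the variance components.
#' @param h2_includes_trial if `TRUE` (default) heritability is
#'   `var_g / (var_g + var_t + var_e)` ("total variance" = all fitted
#'   components); if `FALSE` the trial component is excluded from the
#'   denominator.
#' @return An object of class `trait_summary`: trait name, `mu_hat`,
#'   variance components `var_g`, `var_t`, `var_e`, `h2`, a
#'   `genetic_values` tibble (`accession_id`, `blup`, `genetic_value`),
#'   the log-likelihood trace and a convergence flag.
#' @export
fit_trial_lmm <- function(means, trait = "trait", max_iter = 500, tol = 1e-8,
                          h2_includes_trial = TRUE) {
  means <- as.matrix(means)
  na <- nrow(means); nt <- ncol(means)
  if (na < 2 || nt < 2) stop("need at least 2 accessions and 2 trials")
  obs <- which(!is.na(means), arr.ind = TRUE)
  y <- means[obs]
  nobs <- length(y)
  if (any(rowSums(!is.na(means)) == 0) || any(colSums(!is.na(means)) == 0))
    stop("singular design: an accession or trial has no observations")

  # incidence structure: W = [1 | Za | Zt]
  ia <- obs[, 1]; it <- obs[, 2]
  W <- cbind(1, outer(ia, seq_len(na), "=="), outer(it, seq_len(nt), "=="))
  storage.mode(W) <- "double"
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  ig <- 1 + seq_len(na); itr <- 1 + na + seq_len(nt)

  vtot <- stats::var(y)
  vg <- vt <- vtot / 4
  ve <- vtot / 2
  floor_v <- vtot * 1e-10
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    C <- WtW
    diag(C)[ig] <- diag(WtW)[ig] + ve / vg
    diag(C)[itr] <- diag(WtW)[itr] + ve / vt
    Cinv <- solve(C)
    s <- Cinv %*% Wty
    ghat <- s[ig]; that <- s[itr]

    # restricted log-likelihood via Henderson's identities
    ll <- -0.5 * (nobs * log(ve) + na * log(vg) + nt * log(vt) +
                    as.numeric(determinant(C / ve, logarithm = TRUE)$modulus) +
                    (yty - sum(s * Wty)) / ve)
    ll_trace <- c(ll_trace, ll)

    vg_new <- max((sum(ghat^2) + ve * sum(diag(Cinv)[ig])) / na, floor_v)
    vt_new <- max((sum(that^2) + ve * sum(diag(Cinv)[itr])) / nt, floor_v)
    ve_new <- max((yty - sum(s * Wty)) / (nobs - 1), floor_v)
    # components pinned at the zero floor are excluded from the criterion
    act <- c(vg_new, vt_new, ve_new) > floor_v * 1.01
    delta <- max((abs(c(vg_new - vg, vt_new - vt, ve_new - ve)) /
                    pmax(abs(c(vg, vt, ve)), floor_v))[act], 0)
    vg <- vg_new; vt <- vt_new; ve <- ve_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")

  # BLUPs at the converged components
  C <- WtW
  diag(C)[ig] <- diag(WtW)[ig] + ve / vg
  diag(C)[itr] <- diag(WtW)[itr] + ve / vt
  s <- solve(C, Wty)
  mu_hat <- s[1]
  blup <- as.numeric(s[ig])
  vg_out <- if (vg <= floor_v * 1.01) 0 else vg
  vt_out <- if (vt <= floor_v * 1.01) 0 else vt
  res <- structure(list(trait = trait, mu_hat = mu_hat,
                        var_g = vg_out, var_t = vt_out, var_e = ve,
                        h2 = NA_real_,
                        h2_includes_trial = h2_includes_trial,
                        genetic_values = tibble::tibble(
                          accession_id = rownames(means) %||% as.character(seq_len(na)),
                          blup = blup, genetic_value = mu_hat + blup),
                        loglik = ll_trace, converged = converged,
                        n_iter = length(ll_trace)),
                   class = "trait_summary")
  res$h2 <- heritability(res)
  res
}

#' Heritability from fitted variance components
#'
#' The genotype share of the total fitted variance,
#' `var_g / (var_g + var_t + var_e)`; when the summary was fitted with
#' `h2_includes_trial = FALSE`, the trial component is left out of the
#' denominator.
#'
#' @param summary a [fit_trial_lmm()] result.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(summary) {
  stopifnot(inherits(summary, "trait_summary"))
  denom <- summary$var_g + summary$var_e +
    if (isTRUE(summary$h2_includes_trial)) summary$var_t else 0
  if (denom <= 0) stop("heritability undefined: all variance components are zero")
  summary$var_g / denom
}

#' Per-accession labels for ordinal descriptor traits
#'
#' Conventional-descriptor (CD) traits are 3-10 point manual scores for
#' which a Gaussian trial model is inappropriate; the per-accession label is
#' the modal label across all trials and replicates, ties going to the
#' lower category.
#'
#' @param tbl long-format tibble (`accession_id`, `trial`, `rep`, `trait`,
#'   `value`) whose `value` holds class labels for this trait.
#' @param trait ordinal trait name.
#' @param levels optional class levels, lowest first; defaults to the sorted
#'   unique labels.
#' @return A tibble (`accession_id`, `label`) with `label` an ordered factor.
#' @export
modal_labels <- function(tbl, trait, levels = NULL) {
  sub <- dplyr::filter(tbl, .data$trait == !!trait)
  if (nrow(sub) == 0) stop("trait '", trait, "' not present in table")
  if (is.null(levels)) levels <- sort(unique(as.character(sub$value)))
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$accession_id),
    label = {
      cnt <- table(factor(as.character(.data$value), levels = levels))
      levels[which.max(cnt)]    # first max -> lower category on ties
    },
    .groups = "drop")
  out$label <- factor(out$label, levels = levels, ordered = TRUE)
  out
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf("<trait_summary> %s: var_g=%.4g var_t=%.4g var_e=%.4g H2=%.3f (%s, %d EM iterations)\n",
              x$trait, x$var_g, x$var_t, x$var_e, x$h2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
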
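#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-accession genetic values from a trial-LMM fit
#'
#' @param x a [fit_trial_lmm()] `trait_summary`.
#' @param ... ignored.
#' @return A tibble (`trait`, `accession_id`, `blup`, `genetic_value`).
#' @export
tidy.trait_summary <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(trait = x$trait), x$genetic_values)
}

#' One-row variance-component summary of a trial-LMM fit
#'
#' @param x a [fit_trial_lmm()] `trait_summary`.
#' @param ... ignored.
#' @return A one-row tibble (`trait`, `mu_hat`, `var_g`, `var_t`, `var_e`,
#'   `h2`, `converged`, `n_iter`).
#' @export
glance.trait_summary <- function(x, ...) {
  tibble::tibble(trait = x$trait, mu_hat = x$mu_hat, var_g = x$var_g,
                 var_t = x$var_t, var_e = x$var_e, h2 = x$h2,
                 converged = x$converged, n_iter = x$n_iter)
}

#' Tidy marker effects from an rrBLUP fit
#'
#' @param x a [fit_rrblup()] model.
#' @param ... ignored.
#' @return A tibble (`marker_id`, `effect`).
#' @export
tidy.rrblup <- function(x, ...) {
  tibble::tibble(marker_id = x$marker_ids, effect = unname(x$u_hat))
}

#' One-row summary of an rrBLUP fit
#'
#' @param x a [fit_rrblup()] model.
#' @param ... ignored.
#' @return A one-row tibble (`b_hat`, `lambda`, `var_u`, `var_e`,
#'   `n_markers`, `boundary`).
#' @export
glance.rrblup <- function(x, ...) {
  tibble::tibble(b_hat = x$b_hat, lambda = x$lambda, var_u = x$var_u,
                 var_e = x$var_e, n_markers = length(x$u_hat),
                 boundary = x$boundary)
}

#' Tidy genetic/residual covariances of a multi-trait fit
#'
#' @param x a [fit_multitrait()] model.
#' @param ... ignored.
#' @return A tibble (`component`, `trait_1`, `trait_2`, `covariance`,
#'   `correlation`).
#' @export
tidy.multitrait_model <- function(x, ...) {
  one <- function(S, nm) {
    cc <- stats::cov2cor(S)
    idx <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    tibble::tibble(component = nm,
                   trait_1 = x$trait_names[idx[, 1]],
                   trait_2 = x$trait_names[idx[, 2]],
                   covariance = S[idx], correlation = cc[idx])
  }
  dplyr::bind_rows(one(x$Sigma_g, "genetic"), one(x$Sigma_e, "residual"))
}

#' One-row summary of a multi-trait fit
#'
#' @param x a [fit_multitrait()] model.
#' @param ... ignored.
#' @return A one-row tibble (`n_traits`, `n_accessions`, `converged`,
#'   `n_iter`, `loglik`).
#' @export
glance.multitrait_model <- function(x, ...) {
  tibble::tibble(n_traits = length(x$trait_names),
                 n_accessions = nrow(x$blup_matrix),
                 converged = x$converged, n_iter = length(x$loglik),
                 loglik = x$loglik[length(x$loglik)])
}

#' Per-set records / summary of a cross-validation report
#'
#' `tidy()` returns the per-CV-set long records; `glance()` the mean/sd
#' summary from [summarise_cv()].
#'
#' @param x a [run_cv()] `cv_report`.
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.cv_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) summarise_cv(x)

#' Boxplots of cross-validated predictability metrics
#'
#' One box per metric (faceted by trait for multi-trait reports) over the
#' CV sets.
#'
#' @param object a [run_cv()] `cv_report`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "metric value over CV sets") +
    ggplot2::theme_minimal()
  if (length(unique(df$trait)) > 1)
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$trait))
  p
}

#' Population-structure scatter of genotype principal components
#'
#' PC1 vs PC2 coloured by species, the standard view of a cultivated core
#' with scattered divergent wild groups.
#'
#' @param object a [pca_genotypes()] `gs_pca`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.gs_pca <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$species)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$prop_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$prop_variance[2])) +
    ggplot2::theme_minimal()
}

#' Predictability against tag-SNP subset fraction
#'
#' Line plot of mean Pearson predictability (with one standard deviation
#' ribbon) across tag-subset fractions, built from a named list of
#' [run_cv()] reports.
#'
#' @param reports named list of `cv_report`s; names are the fractions.
#' @return A ggplot object.
#' @export
plot_tag_fraction_curve <- function(reports) {
  df <- purrr::imap_dfr(reports, function(r, nm) {
    s <- summarise_cv(r)
    s <- dplyr::filter(s, .data$metric == "pearson")
    tibble::tibble(fraction = as.numeric(nm), mean = s$mean, sd = s$sd)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "tag-SNP subset fraction",
                  y = "mean Pearson predictability") +
    ggplot2::theme_minimal()
}
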
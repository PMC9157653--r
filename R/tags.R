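#' Select ranked tag SNPs by greedy maximum LD coverage
#'
#' Within each chromosome, a variant "covers" itself and every variant
#' within `window_snps` positions whose squared dosage correlation with it
#' is at least `r2_tag`. Tags are chosen greedily: at each step the variant
#' covering the most not-yet-covered variants is made a tag (ties broken
#' toward the lower position), its covered set is marked, and the process
#' repeats until every variant is covered. Per-chromosome selection orders
#' are interleaved across chromosomes (all rank-1 tags first, then rank-2,
#' ...) so that any prefix of the genome-wide list is representative of the
#' whole genome.
#'
#' @param G a complete, MAF-filtered [geno_matrix()].
#' @param r2_tag r-squared threshold defining coverage (default 0.8).
#' @param window_snps coverage window width in SNPs (default 100).
#' @return An object of class `tag_selection`: list with `tag_ids` (ranked),
#'   `covered_by` (named character vector mapping every non-tag variant to
#'   its tag), `r2_threshold`, `window_snps` and a `table` tibble
#'   (`tag_id`, `chrom`, `rank`, `n_covered`).
#' @export
select_tag_snps <- function(G, r2_tag = 0.8, window_snps = 100) {
  stopifnot(inherits(G, "geno_matrix"), r2_tag > 0, r2_tag <= 1)
  check_complete(G, "tag selection")
  chroms <- unique(G$map$chrom)
  per_chrom <- vector("list", length(chroms))
  covered_by <- character(0)
  for (ci in seq_along(chroms)) {
    idx <- which(G$map$chrom == chroms[ci])
    mc <- length(idx)
    Xs <- scaled_dosage(G$dosage[, idx, drop = FALSE])
    # banded adjacency: pairs within window with r^2 >= threshold
    nbr <- vector("list", mc)
    for (d in seq_len(min(window_snps, mc - 1))) {
      a <- seq_len(mc - d)
      r2v <- colSums(Xs[, a, drop = FALSE] * Xs[, a + d, drop = FALSE])^2
      hit <- which(r2v >= r2_tag)
      for (h in hit) {
        nbr[[h]] <- c(nbr[[h]], h + d)
        nbr[[h + d]] <- c(nbr[[h + d]], h)
      }
    }
    # gain[i] = number of still-uncovered variants i would cover (incl. itself)
    uncovered <- rep(TRUE, mc)
    gain <- 1L + vapply(nbr, length, integer(1))
    tags <- integer(0); ncov <- integer(0)
    cov_tag <- integer(mc)
    while (any(uncovered)) {
      best <- which.max(gain)                      # which.max: tie -> lower position
      newly <- unique(c(best, nbr[[best]]))
      newly <- newly[uncovered[newly]]
      tags <- c(tags, best)
      ncov <- c(ncov, length(newly))
      uncovered[newly] <- FALSE
      cov_tag[newly] <- best
      for (u in newly) {
        gain[u] <- gain[u] - 1L
        gain[nbr[[u]]] <- gain[nbr[[u]]] - 1L
      }
    }
    pruned <- setdiff(seq_len(mc), tags)
    covered_by <- c(covered_by, stats::setNames(
      G$map$variant_id[idx[cov_tag[pruned]]], G$map$variant_id[idx[pruned]]))
    per_chrom[[ci]] <- tibble::tibble(tag_id = G$map$variant_id[idx[tags]],
                                      chrom = chroms[ci],
                                      rank_within = seq_along(tags),
                                      n_covered = ncov)
  }
  tab <- dplyr::arrange(dplyr::bind_rows(per_chrom), .data$rank_within,
                        match(.data$chrom, chroms))
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("tag_id", "chrom", "rank", "n_covered")]
  structure(list(tag_ids = tab$tag_id, covered_by = covered_by,
                 r2_threshold = r2_tag, window_snps = as.integer(window_snps),
                 table = tab),
            class = "tag_selection")
}

#' @export
print.tag_selection <- function(x, ...) {
  cat(sprintf("<tag_selection> %d tags covering %d variants (r2 >= %g, window %d SNPs)\n",
              length(x$tag_ids), length(x$tag_ids) + length(x$covered_by),
              x$r2_threshold, x$window_snps))
  invisible(x)
}

#' Take the top-ranked fraction of tag SNPs
#'
#' Returns the first `ceiling(fraction * n_tags)` tags in genome-wide rank
#' order. Subsets are nested across fractions: a smaller fraction is always
#' a prefix (hence subset) of a larger one.
#'
#' @param sel a [select_tag_snps()] result.
#' @param fraction fraction of tags to keep, in (0, 1]. The study design
#'   uses \{0.005, 0.01, 0.1, 0.25, 0.5, 0.75, 1\}.
#' @return Character vector of variant ids.
#' @export
tag_subset <- function(sel, fraction) {
  stopifnot(inherits(sel, "tag_selection"), fraction > 0, fraction <= 1)
  utils::head(sel$tag_ids, ceiling(fraction * length(sel$tag_ids)))
}

#' Principal component analysis of a SNP panel
#'
#' Dosages are column-centred and scaled to unit variance (monomorphic
#' columns are dropped first), then decomposed by SVD via
#' [stats::prcomp()].
#'
#' @param G a complete [geno_matrix()].
#' @param k number of components, `k < min(n_accessions, n_polymorphic_snps)`.
#' @return An object of class `gs_pca`: list with `scores` (tibble:
#'   `accession_id`, `species`, `is_wild`, `PC1..PCk`), `explained_variance`
#'   (the k component variances) and `prop_variance` (their share of the
#'   total).
#' @export
pca_genotypes <- function(G, k = 10) {
  stopifnot(inherits(G, "geno_matrix"))
  check_complete(G, "PCA")
  X <- G$dosage
  poly <- apply(X, 2, stats::sd) > 0
  X <- X[, poly, drop = FALSE]
  if (k >= min(nrow(X), ncol(X)))
    stop("k must be smaller than min(accessions, polymorphic SNPs)")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE, rank. = k)
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(G$meta, scores)
  structure(list(scores = scores,
                 explained_variance = pc$sdev[seq_len(k)]^2,
                 prop_variance = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)),
            class = "gs_pca")
}

#' @export
print.gs_pca <- function(x, ...) {
  cat(sprintf("<gs_pca> %d accessions, %d components; PC1 explains %.1f%% of variance\n",
              nrow(x$scores), length(x$explained_variance), 100 * x$prop_variance[1]))
  invisible(x)
}
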
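#' Remove variants with excessive missingness
#'
#' Variants whose fraction of missing calls exceeds `max_missing` are
#' removed; a variant missing in exactly that fraction is kept ("at most").
#' Variant order is preserved.
#'
#' @param G a [geno_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return A filtered [geno_matrix()].
#' @export
filter_missingness <- function(G, max_missing = 0.5) {
  stopifnot(inherits(G, "geno_matrix"), max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(G$dosage))
  keep <- frac <= max_missing
  if (!any(keep)) warning("all variants removed by missingness filter")
  G[, which(keep)]
}

#' Impute missing calls by the per-variant modal dosage
#'
#' Each missing entry is replaced by the most frequent observed dosage of
#' its variant; ties go to the lower dosage. A simple stand-in for
#' haplotype-based imputation that keeps allele frequencies approximately
#' intact.
#'
#' @param G a [geno_matrix()]; every variant must have at least one observed
#'   call.
#' @return A complete [geno_matrix()].
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  dos <- G$dosage
  nmiss <- colSums(is.na(dos))
  if (any(nmiss == nrow(dos)))
    stop("variant(s) with no observed calls; run filter_missingness() first")
  for (j in which(nmiss > 0)) {
    x <- dos[, j]
    cnt <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    dos[is.na(x), j] <- which.max(cnt) - 1L   # which.max takes first max: tie -> lower dosage
  }
  geno_matrix(dos, G$map, G$meta)
}

#' Remove variants with low minor allele frequency
#'
#' MAF is `min(p, 1 - p)` with `p = sum(dosage) / (2 * n_observed)`,
#' computed on observed calls. Variants with MAF strictly below `min_maf`
#' are removed.
#'
#' @param G a [geno_matrix()].
#' @param min_maf minimum MAF retained (default 0.05).
#' @return A filtered [geno_matrix()].
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  stopifnot(inherits(G, "geno_matrix"), min_maf >= 0, min_maf <= 0.5)
  p <- colMeans(G$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  G[, which(maf >= min_maf)]
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation between two variants'
#' dosage vectors, phase-free and valid for unphased data.
#'
#' @param G a complete [geno_matrix()].
#' @param i,j variant indices or variant ids.
#' @return A value in \[0, 1\].
#' @export
ld_r2 <- function(G, i, j) {
  stopifnot(inherits(G, "geno_matrix"))
  check_complete(G, "LD computation")
  if (is.character(i)) i <- match(i, G$map$variant_id)
  if (is.character(j)) j <- match(j, G$map$variant_id)
  x <- G$dosage[, i]; y <- G$dosage[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("LD undefined for monomorphic variants")
  stats::cor(x, y)^2
}

# internal: accessions x m matrix scaled so crossprod gives correlations;
# monomorphic columns get all-zero scores (r^2 treated as 0 against them)
scaled_dosage <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu)
  ok <- sd > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sd[ok] * sqrt(nrow(X) - 1), "/")
  Xs[, !ok] <- 0
  Xs
}

#' Prune near-duplicate variants by an LD filter
#'
#' Greedy left-to-right pass within each chromosome: a variant is dropped if
#' its squared dosage correlation with any previously retained variant in a
#' sliding window of `window_snps` original positions reaches `r2`. With the
#' default `r2 = 0.999` this removes effectively redundant SNPs while
#' keeping one representative per duplicate run.
#'
#' @param G a complete [geno_matrix()].
#' @param r2 r-squared threshold at or above which a variant is redundant.
#' @param window_snps window width, in number of SNPs.
#' @return A pruned [geno_matrix()].
#' @export
prune_redundant <- function(G, r2 = 0.999, window_snps = 100) {
  stopifnot(inherits(G, "geno_matrix"), r2 > 0, r2 <= 1)
  check_complete(G, "LD pruning")
  keep <- logical(ncol(G$dosage))
  for (ch in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == ch)
    Xs <- scaled_dosage(G$dosage[, idx, drop = FALSE])
    kept <- integer(0)
    for (jj in seq_along(idx)) {
      recent <- kept[kept >= jj - window_snps]
      drop <- FALSE
      if (length(recent) > 0) {
        r2s <- drop(crossprod(Xs[, recent, drop = FALSE], Xs[, jj]))^2
        drop <- any(r2s >= r2)
      }
      if (!drop) {
        kept <- c(kept, jj)
        keep[idx[jj]] <- TRUE
      }
    }
  }
  G[, which(keep)]
}
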
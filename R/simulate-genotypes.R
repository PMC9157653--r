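#' Specification of a synthetic Solanaceous diversity panel
#'
#' Describes the population emulated by [simulate_genotypes()]: a large
#' cultivated group plus several small, divergent wild-species groups, with
#' tGBS-like SNP density and local linkage disequilibrium. Defaults mirror a
#' tomato panel: 146 cultivated accessions and 34 wild accessions spread over
#' 7 species, 10,000 SNPs on 12 chromosomes.
#'
#' Wild-group allele frequencies are drawn around a shared ancestral
#' frequency vector by the Balding-Nichols construction with differentiation
#' `fst_wild`; the cultivated group uses the ancestral frequencies directly.
#' LD is produced by a latent stationary AR(1) Gaussian process along each
#' chromosome. `ld_rho` is calibrated on the dosage scale: thresholding a
#' Gaussian to a binary allele shrinks correlations (by the arcsine law at
#' balanced frequencies), so the latent lag-one coefficient is set to
#' `sin(pi * ld_rho / 2)`, which makes the realised correlation between
#' adjacent SNP dosages approximately `ld_rho` at similar allele
#' frequencies. For the same reason ancestral frequencies follow a probit
#' AR(1) with the same persistence: adjacent SNPs in strong LD have similar
#' frequencies, as in real panels, and without this the frequency mismatch
#' alone would cap attainable r-squared well below 1.
#'
#' @param n_cultivated number of cultivated accessions.
#' @param wild_group_sizes integer vector, one entry per wild species.
#' @param n_snps total number of SNPs, split evenly across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param ld_rho target correlation between adjacent SNP dosages, in
#'   \[0, 1).
#' @param fst_wild Balding-Nichols differentiation between the ancestral pool
#'   and each wild species, in (0, 1).
#' @param maf_floor minimum ancestral allele frequency, in (0, 0.5).
#' @param missing_rate fraction of dosage entries set missing, in \[0, 1).
#' @param seed integer RNG seed; identical specs give identical panels.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_cultivated = 146,
                            wild_group_sizes = c(12, 11, 3, 3, 2, 2, 1),
                            n_snps = 10000,
                            n_chromosomes = 12,
                            ld_rho = 0.95,
                            fst_wild = 0.3,
                            maf_floor = 0.05,
                            missing_rate = 0.1,
                            seed = 1L) {
  stopifnot(n_cultivated >= 1, all(wild_group_sizes >= 0),
            n_snps >= 1, n_chromosomes >= 1,
            ld_rho >= 0, ld_rho < 1,
            fst_wild > 0, fst_wild < 1,
            maf_floor > 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cultivated = as.integer(n_cultivated),
                 wild_group_sizes = as.integer(wild_group_sizes),
                 n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 ld_rho = ld_rho, fst_wild = fst_wild,
                 maf_floor = maf_floor, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a structured SNP panel with local LD
#'
#' Generates an accessions x SNPs dosage matrix under the model described in
#' [population_spec()]. SNPs are assigned evenly to chromosomes with
#' increasing 1-based positions (1 kb spacing). For each haplotype a latent
#' stationary AR(1) Gaussian series is thresholded at the group-specific
#' allele-frequency quantile, and two haplotypes are summed to a dosage.
#' Missing calls are then inserted uniformly at `missing_rate`.
#'
#' @param spec a [population_spec()].
#' @return A [geno_matrix()] with metadata labelling cultivated and wild
#'   accessions (`species` is `"cultivated"` or `"wild_<k>"`).
#' @export
simulate_genotypes <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  wild_sizes <- spec$wild_group_sizes[spec$wild_group_sizes > 0]
  n_wild_groups <- length(wild_sizes)
  n <- spec$n_cultivated + sum(wild_sizes)
  m <- spec$n_snps

  # group membership: cultivated block first, then wild species blocks
  species <- c(rep("cultivated", spec$n_cultivated),
               rep(sprintf("wild_%d", seq_len(n_wild_groups)), wild_sizes))
  group <- match(species, c("cultivated", sprintf("wild_%d", seq_len(n_wild_groups))))

  # latent persistence: invert the arcsine shrinkage so adjacent dosages
  # correlate at ~ld_rho rather than at the (much weaker) thresholded value
  rho <- sin(pi * spec$ld_rho / 2)
  innov_sd <- sqrt(1 - rho^2)

  # chromosome assignment: m split as evenly as possible, positions 1-based
  per_chrom <- diff(round(seq(0, m, length.out = spec$n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(spec$n_chromosomes)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) seq_len(k) * 1000L), use.names = FALSE)

  # ancestral frequencies: probit AR(1) along each chromosome (same
  # persistence as the haplotype process), squashed into the MAF band;
  # wild groups drawn by Balding-Nichols around them
  ar1_series <- function() {
    x <- stats::rnorm(m)
    if (rho > 0) {
      col0 <- 0L
      for (k in seq_along(per_chrom)) {
        mc <- per_chrom[k]
        if (mc > 1L) for (j in 2:mc) {
          x[col0 + j] <- rho * x[col0 + j - 1L] + innov_sd * x[col0 + j]
        }
        col0 <- col0 + mc
      }
    }
    x
  }
  p0 <- spec$maf_floor + (1 - 2 * spec$maf_floor) * stats::pnorm(ar1_series())
  freq <- matrix(0, nrow = 1 + n_wild_groups, ncol = m)
  freq[1, ] <- p0
  if (n_wild_groups > 0) {
    # Balding-Nichols marginals through a Gaussian copula with the same
    # AR(1) persistence, so wild-group frequencies keep local LD intact
    shape_scale <- (1 - spec$fst_wild) / spec$fst_wild
    for (g in seq_len(n_wild_groups)) {
      u <- stats::pnorm(ar1_series())
      fg <- stats::qbeta(u, p0 * shape_scale, (1 - p0) * shape_scale)
      freq[g + 1, ] <- pmin(pmax(fg, 1e-3), 1 - 1e-3)
    }
  }
  thresh <- stats::qnorm(freq)  # latent threshold per group x SNP

  # latent AR(1) per chromosome, shared recursion across all 2n haplotypes
  hap_group <- rep(group, each = 2L)
  dosage <- matrix(0L, nrow = n, ncol = m)
  col0 <- 0L
  for (k in seq_along(per_chrom)) {
    mc <- per_chrom[k]
    if (mc == 0L) next
    z <- matrix(0, nrow = 2L * n, ncol = mc)
    z[, 1] <- stats::rnorm(2L * n)
    if (mc > 1L) {
      eps <- matrix(stats::rnorm(2L * n * (mc - 1L), sd = innov_sd), nrow = 2L * n)
      for (j in 2:mc) z[, j] <- rho * z[, j - 1L] + eps[, j - 1L]
    }
    alle <- z <= thresh[hap_group, col0 + seq_len(mc), drop = FALSE]
    dosage[, col0 + seq_len(mc)] <- alle[seq(1, 2L * n, by = 2L), , drop = FALSE] +
      alle[seq(2, 2L * n, by = 2L), , drop = FALSE]
    col0 <- col0 + mc
  }

  if (spec$missing_rate > 0) {
    miss <- which(stats::runif(length(dosage)) < spec$missing_rate)
    dosage[miss] <- NA
  }

  rownames(dosage) <- sprintf("ACC%04d", seq_len(n))
  colnames(dosage) <- sprintf("SNP%06d", seq_len(m))
  map <- tibble::tibble(variant_id = colnames(dosage), chrom = chrom, pos = pos,
                        ref = "A", alt = "C")
  meta <- tibble::tibble(accession_id = rownames(dosage), species = species,
                         is_wild = species != "cultivated")
  geno_matrix(dosage, map, meta)
}
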
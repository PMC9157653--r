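test_that("VCF round-trip preserves dosages, map and GT coding", {
  dos <- matrix(c(0, 1, 2, NA, 1,
                  2, 2, 0, 1, 0,
                  1, 0, NA, 2, 1,
                  0, 0, 1, 1, 2,
                  2, 1, 0, 0, NA,
                  1, 2, 1, 0, 0,
                  0, NA, 2, 1, 1,
                  2, 0, 1, 2, 0,
                  1, 1, 0, NA, 2,
                  0, 2, 2, 1, 1), nrow = 5)
  G <- toy_geno(dos, chrom = rep(c("1", "2"), each = 5),
                pos = rep(1:5 * 100, 2))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, path)
  # GT strings encode dosage as expected
  lines <- readLines(path)
  first <- strsplit(lines[grep("^1\t100\t", lines)], "\t")[[1]]
  expect_equal(first[10:14], c("0/0", "0/1", "1/1", "./.", "0/1"))
  G2 <- read_vcf(path)
  expect_equal(unname(G2$dosage), unname(G$dosage))
  expect_equal(G2$map$pos, G$map$pos)
  expect_equal(G2$map$chrom, G$map$chrom)
})

test_that("non-SNP and multi-allelic VCF records are skipped with a message", {
  path <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", "S2", sep = "\t"))
  rec <- function(pos, ref, alt) {
    paste("1", pos, paste0("v", pos), ref, alt, ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t")
  }
  writeLines(c(hdr, rec(100, "A", "G"), rec(200, "A", "G,T"),
               vapply(3:10, function(i) rec(i * 100, "C", "T"), "")), path)
  expect_message(G <- read_vcf(path), "1 multi-allelic or non-SNP")
  expect_equal(ncol(G$dosage), 9)
})

test_that("dosage matrix serialisation round-trips including missing calls", {
  G <- simulate_genotypes(population_spec(
    n_cultivated = 12, wild_group_sizes = c(3), n_snps = 30,
    n_chromosomes = 2, missing_rate = 0.15, seed = 31))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage(G, path)
  G2 <- read_dosage(path)
  expect_equal(unname(G2$dosage), unname(G$dosage))
  expect_equal(G2$map, G$map)
  expect_equal(G2$meta, G$meta)
})

test_that("missingness filter keeps the boundary and respects 'at most'", {
  dos <- matrix(c(NA, NA, NA, 0,   # 3/4 missing -> removed at 0.5
                  NA, NA, 1, 2,    # 2/4 missing -> kept (boundary)
                  0, 1, 2, 1), nrow = 4)
  G <- toy_geno(dos)
  Gf <- filter_missingness(G, 0.5)
  expect_equal(ncol(Gf$dosage), 2)
  expect_equal(Gf$map$variant_id, G$map$variant_id[2:3])
  expect_equal(ncol(filter_missingness(G, 1)$dosage), 3)
})

test_that("modal imputation fills missing calls with the tie going low", {
  dos <- cbind(c(0, 0, 2, NA), c(0, 2, NA, NA), c(1, 1, 2, 0))
  G <- toy_geno(dos)
  Gi <- impute_missing(G)
  expect_equal(unname(Gi$dosage[4, 1]), 0)      # mode
  expect_equal(unname(Gi$dosage[3:4, 2]), c(0, 0))  # 0/2 tie -> 0
  expect_false(anyNA(Gi$dosage))
  expect_identical(impute_missing(Gi)$dosage, Gi$dosage)
  expect_error(impute_missing(toy_geno(cbind(c(NA, NA), c(0, 1)))),
               "no observed calls")
})

test_that("MAF filter uses min(p, 1-p) over observed calls", {
  dos <- cbind(c(0, 0, 0, 0, 0, 2),  # p = 2/12 -> kept
               c(0, 0, 0, 0, 0, 0),  # monomorphic -> removed
               c(0, 0, 0, 0, 0, 1),  # p = 1/12 = 0.083 -> kept at 0.05
               c(2, 2, 2, 2, 2, 1))  # p = 11/12, MAF 1/12 -> kept
  G <- toy_geno(dos)
  Gf <- filter_maf(G, 0.05)
  expect_equal(Gf$map$variant_id, G$map$variant_id[c(1, 3, 4)])
  expect_equal(ncol(filter_maf(G, 0.15)$dosage), 1)
  expect_equal(ncol(filter_maf(G, 0.4)$dosage), 0)
})

test_that("LD r2 is the squared dosage correlation", {
  set.seed(41)
  x <- sample(0:2, 40, replace = TRUE)
  G <- toy_geno(cbind(x, x, 2 - x, sample(0:2, 40, replace = TRUE),
                      rep(1, 40)))
  expect_equal(ld_r2(G, 1, 2), 1)
  expect_equal(ld_r2(G, 1, 3), 1)   # perfect repulsion
  expect_error(ld_r2(G, 1, 5), "monomorphic")
  # independent variants: near-zero r2 on average at n = 500
  set.seed(42)
  Gind <- toy_geno(matrix(rbinom(500 * 40, 2, 0.4), nrow = 500))
  r2s <- vapply(seq_len(19), function(j) ld_r2(Gind, j, j + 1), numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("redundancy pruning drops near-duplicates greedily left-to-right", {
  set.seed(43)
  x <- rbinom(30, 2, 0.5); y <- rbinom(30, 2, 0.5); z <- rbinom(30, 2, 0.5)
  G <- toy_geno(cbind(x, x, y, x, z))
  Gp <- prune_redundant(G, r2 = 0.999)
  expect_equal(Gp$map$variant_id, G$map$variant_id[c(1, 3, 5)])
  # independent matrix untouched
  Gind <- toy_geno(matrix(rbinom(200 * 20, 2, 0.4), nrow = 200))
  expect_equal(ncol(prune_redundant(Gind)$dosage), 20)
  # idempotence of the full QC pipeline
  G0 <- simulate_genotypes(population_spec(
    n_cultivated = 60, wild_group_sizes = integer(0), n_snps = 400,
    n_chromosomes = 2, missing_rate = 0.1, seed = 44))
  qc <- function(g) prune_redundant(filter_maf(impute_missing(
    filter_missingness(g, 0.5)), 0.05), 0.999)
  G1 <- qc(G0)
  expect_identical(qc(G1)$dosage, G1$dosage)
})

test_that("tag selection covers every variant at the r2 threshold", {
  set.seed(45)
  x <- rbinom(50, 2, 0.5)
  G <- toy_geno(cbind(x, x, rbinom(50, 2, 0.4)))
  sel <- select_tag_snps(G, r2_tag = 0.8)
  expect_equal(length(sel$tag_ids), 2)
  expect_equal(unname(sel$covered_by[G$map$variant_id[2]]),
               G$map$variant_id[1])
  # fully independent: every variant its own tag
  Gind <- toy_geno(matrix(rbinom(300 * 15, 2, 0.4), nrow = 300))
  expect_equal(length(select_tag_snps(Gind)$tag_ids), 15)
  # exhaustive coverage post-check on a high-LD panel
  Gld <- simulate_genotypes(population_spec(
    n_cultivated = 120, wild_group_sizes = integer(0), n_snps = 600,
    n_chromosomes = 3, ld_rho = 0.95, missing_rate = 0, seed = 46))
  Gld <- filter_maf(Gld, 0.05)
  sel2 <- select_tag_snps(Gld, r2_tag = 0.8)
  expect_lt(length(sel2$tag_ids), ncol(Gld$dosage))
  chrom_of <- stats::setNames(Gld$map$chrom, Gld$map$variant_id)
  for (v in names(sel2$covered_by)) {
    tg <- sel2$covered_by[[v]]
    expect_identical(chrom_of[[v]], chrom_of[[tg]])
    expect_gte(ld_r2(Gld, v, tg), 0.8)
  }
})

test_that("tag subsets are nested prefixes of the rank order", {
  Gld <- simulate_genotypes(population_spec(
    n_cultivated = 100, wild_group_sizes = integer(0), n_snps = 400,
    n_chromosomes = 2, ld_rho = 0.95, missing_rate = 0, seed = 47))
  sel <- select_tag_snps(filter_maf(Gld, 0.05))
  fr <- c(0.005, 0.01, 0.1, 0.25, 0.5, 0.75, 1)
  subsets <- lapply(fr, function(f) tag_subset(sel, f))
  for (i in seq_len(length(fr) - 1))
    expect_true(all(subsets[[i]] %in% subsets[[i + 1]]))
  expect_equal(subsets[[length(fr)]], sel$tag_ids)
  expect_length(tag_subset(structure(list(tag_ids = sprintf("t%d", 1:200)),
                                     class = "tag_selection"), 0.005), 1)
})

test_that("tag selection of the default panel falls in the expected envelope", {
  # full-density default conditions (ld_rho 0.95) give a tag fraction in the
  # 10-60% band; weaker LD settings approach 100% because thresholded
  # dosages cannot reach r2 = 0.8 between unlike-frequency neighbours
  # complete genotypes: single-SNP modal imputation attenuates pairwise LD
  # (unlike the haplotype imputation real pipelines use), so tagging
  # statistics are assessed on the panel before missingness is added
  G <- cached("default_tags", {
    g <- simulate_genotypes(population_spec(n_snps = 4000, missing_rate = 0,
                                            seed = 48))
    filter_maf(g, 0.05)
  })
  sel <- select_tag_snps(G, r2_tag = 0.8)
  frac <- length(sel$tag_ids) / ncol(G$dosage)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.60)
})

test_that("PCA scores are orthogonal and separate cultivated from wild", {
  G <- structured_panel()
  pc <- pca_genotypes(G, k = 4)
  S <- as.matrix(pc$scores[, paste0("PC", 1:4)])
  off <- crossprod(S); diag(off) <- 0
  expect_lt(max(abs(off)) / max(crossprod(S)), 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-8))
  # a single divergent wild group at fst 0.3 separates on PC1-PC2 with a
  # positive mean silhouette
  Gw <- simulate_genotypes(population_spec(
    n_cultivated = 100, wild_group_sizes = 30, n_snps = 3000,
    n_chromosomes = 6, fst_wild = 0.3, missing_rate = 0, seed = 103))
  pcw <- pca_genotypes(Gw, k = 2)
  Sw <- as.matrix(pcw$scores[, c("PC1", "PC2")])
  dmat <- as.matrix(stats::dist(Sw))
  wildw <- pcw$scores$is_wild
  sil <- vapply(seq_len(nrow(Sw)), function(i) {
    a <- mean(dmat[i, wildw == wildw[i] & seq_len(nrow(Sw)) != i])
    b <- mean(dmat[i, wildw != wildw[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # duplicated accessions get identical scores
  dos2 <- G$dosage[c(1, 1, 2:30), ]
  meta2 <- G$meta[c(1, 1, 2:30), ]
  meta2$accession_id <- sprintf("A%02d", seq_len(31))
  rownames(dos2) <- meta2$accession_id
  G2 <- geno_matrix(dos2, G$map, meta2)
  pc2 <- pca_genotypes(G2, k = 2)
  expect_equal(pc2$scores$PC1[1], pc2$scores$PC1[2], tolerance = 1e-10)
  expect_error(pca_genotypes(G, k = 200), "k must be smaller")
})
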
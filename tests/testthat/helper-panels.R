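# shared simulated panels, built once per test run
panel_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(panel_cache[[key]])) panel_cache[[key]] <- force(expr)
  panel_cache[[key]]
}

# small complete panel, no structure: 100 cultivated x 600 SNPs
small_panel <- function() cached("small", {
  simulate_genotypes(population_spec(
    n_cultivated = 100, wild_group_sizes = integer(0), n_snps = 600,
    n_chromosomes = 4, missing_rate = 0, seed = 101))
})

# structured panel: cultivated + 7 wild groups, complete
structured_panel <- function() cached("structured", {
  simulate_genotypes(population_spec(
    n_cultivated = 120, wild_group_sizes = c(6, 6, 5, 5, 4, 4, 4),
    n_snps = 1200, n_chromosomes = 6, fst_wild = 0.3, missing_rate = 0,
    seed = 102))
})

# toy dosage matrix with known values
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  map <- tibble::tibble(
    variant_id = sprintf("V%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq_len(m), ref = "A", alt = "C")
  colnames(dosage) <- map$variant_id
  rownames(dosage) <- NULL
  geno_matrix(dosage, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
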
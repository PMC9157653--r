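#' Genotype matrix container
#'
#' Holds an accessions x SNPs alternate-allele dosage matrix (values 0, 1, 2
#' or `NA` for missing calls) together with a variant map (chromosome,
#' 1-based position, ref/alt alleles) and per-accession metadata (species
#' label and cultivated/wild status).
#'
#' @param dosage integer/numeric matrix, accessions in rows, SNPs in columns,
#'   values in \{0, 1, 2, NA\}. Row names are accession ids, column names
#'   variant ids; if absent they are generated.
#' @param map tibble with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `dosage`. Positions must be strictly increasing
#'   within each chromosome.
#' @param meta tibble with columns `accession_id`, `species`, `is_wild`,
#'   one row per row of `dosage`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `map`, `meta`.
#' @export
geno_matrix <- function(dosage, map = NULL, meta = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (n < 1L) stop("dosage matrix must have at least one accession")
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("ACC%04d", seq_len(n))
  if (is.null(colnames(dosage)) && m > 0L) colnames(dosage) <- sprintf("SNP%06d", seq_len(m))
  if (is.null(map)) {
    map <- tibble::tibble(variant_id = colnames(dosage), chrom = "1",
                          pos = seq_len(m), ref = "A", alt = "C")
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(accession_id = rownames(dosage),
                           species = NA_character_, is_wild = NA)
  }
  map <- tibble::as_tibble(map)
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(map)),
            all(c("accession_id", "species", "is_wild") %in% names(meta)))
  if (nrow(map) != m) stop("map must have one row per variant")
  if (nrow(meta) != n) stop("meta must have one row per accession")
  if (anyDuplicated(map$variant_id)) stop("variant ids must be unique")
  if (anyDuplicated(meta$accession_id)) stop("accession ids must be unique")
  colnames(dosage) <- map$variant_id
  rownames(dosage) <- meta$accession_id
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosage = dosage, map = map, meta = meta), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d accessions x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * nmiss / length(x$dosage)))
  if (any(!is.na(x$meta$is_wild))) {
    cat(sprintf("  %d cultivated / %d wild accessions\n",
                sum(!x$meta$is_wild, na.rm = TRUE), sum(x$meta$is_wild, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i accession selector (indices, logicals or accession ids).
#' @param j variant selector (indices, logicals or variant ids).
#' @param ... ignored.
#' @return A `geno_matrix` restricted to the selected accessions/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$meta$accession_id)
  if (is.character(j)) j <- match(j, x$map$variant_id)
  if (anyNA(i) || anyNA(j)) stop("unknown accession or variant id in subset")
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE],
              x$meta[i, , drop = FALSE])
}

# internal: error unless the matrix has no missing calls
check_complete <- function(G, what = "this operation") {
  if (anyNA(G$dosage)) {
    stop("genotype matrix contains missing calls; run impute_missing() before ", what)
  }
  invisible(G)
}
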
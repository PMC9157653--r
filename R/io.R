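#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only, and maps
#' diploid GT calls to alternate-allele dosages: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, missing (`./.` or `.`) to `NA`. Multi-allelic or non-SNP
#' records are skipped with a message reporting the count.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param meta optional accession metadata tibble (`accession_id`, `species`,
#'   `is_wild`); defaults to unknown species/status.
#' @return A [geno_matrix()]. Accessions correspond to VCF sample columns.
#' @export
read_vcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) message(n_skip, " multi-allelic or non-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alleles <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), NULL))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(code[alleles], nrow = nrow(gt)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"])[is.na(ids) | ids == "."]
  map <- tibble::tibble(variant_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"])
  colnames(dos) <- map$variant_id
  geno_matrix(dos, map, meta)
}

#' Write a genotype matrix to a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with a GT FORMAT field; dosages map back to
#' unphased genotypes (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, `NA -> ./.`), so
#' `read_vcf(write_vcf(G))` reproduces `G`'s dosages on any data.
#'
#' @param G a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(G$dosage), ncol = ncol(G$dosage))
  obs <- !is.na(G$dosage)
  gt[obs] <- gt_code[G$dosage[obs] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=gsolanum",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$meta$accession_id), collapse = "\t"))
  body <- paste(G$map$chrom, G$map$pos, G$map$variant_id, G$map$ref, G$map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a delimited dosage matrix with its variant map
#'
#' The dosage file is a TSV with accessions in rows (first column
#' `accession_id`) and variants in columns; missing calls are empty cells.
#' The variant map is written alongside as `<path>.map` (columns
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`) and accession metadata as
#' `<path>.meta`.
#'
#' @param G a [geno_matrix()].
#' @param path dosage file path.
#' @return `write_dosage()` returns `path` invisibly; `read_dosage()` a
#'   [geno_matrix()].
#' @export
write_dosage <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  tab <- tibble::as_tibble(G$dosage)
  tab <- dplyr::bind_cols(tibble::tibble(accession_id = G$meta$accession_id), tab)
  readr::write_tsv(tab, path, na = "")
  readr::write_tsv(G$map, paste0(path, ".map"))
  readr::write_tsv(G$meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  map <- readr::read_tsv(paste0(path, ".map"), show_col_types = FALSE,
                         col_types = readr::cols(chrom = readr::col_character()))
  meta <- readr::read_tsv(paste0(path, ".meta"), show_col_types = FALSE)
  dos <- as.matrix(tab[, -1])
  rownames(dos) <- tab$accession_id
  geno_matrix(dos, map, meta)
}

#' Serialise a tag-SNP selection
#'
#' Three-column TSV (`tag_id`, `rank`, `n_covered`) in genome-wide rank
#' order, with the r-squared threshold and window recorded as `#` header
#' lines.
#'
#' @param sel a [select_tag_snps()] result.
#' @param path output path.
#' @return `path` invisibly; `read_tag_selection()` returns a tibble with
#'   attributes `r2_threshold` and `window_snps`.
#' @export
write_tag_selection <- function(sel, path) {
  stopifnot(inherits(sel, "tag_selection"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#r2_threshold=%.17g", sel$r2_threshold), con)
  writeLines(sprintf("#window_snps=%d", sel$window_snps), con)
  writeLines("tag_id\trank\tn_covered", con)
  writeLines(sprintf("%s\t%d\t%d", sel$table$tag_id, sel$table$rank,
                     sel$table$n_covered), con)
  invisible(path)
}

#' @rdname write_tag_selection
#' @export
read_tag_selection <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- readr::read_tsv(paste(lines[!startsWith(lines, "#")], collapse = "\n"),
                         show_col_types = FALSE)
  attr(tab, "r2_threshold") <- as.numeric(sub("#r2_threshold=", "", hdr[1]))
  attr(tab, "window_snps") <- as.integer(sub("#window_snps=", "", hdr[2]))
  tab
}
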
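#' Genotype matrix container
#'
#' An `epi_geno` object holds a samples x SNPs matrix of minor-allele dosage
#' codes together with per-SNP metadata. Codes count copies of the designated
#' effect allele (by convention BIM allele 1, usually the minor allele):
#' 0, 1 or 2, with `NA` for a missing call.
#'
#' @param codes integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`. Row names (if present) are taken as sample IDs.
#' @param snps data frame of per-SNP metadata with columns `snp_id`,
#'   `chr`, `pos`, `allele1`, `allele2`. `pos` is 1-based.
#' @param samples character vector of sample IDs; defaults to
#'   `rownames(codes)` or `S1..Sn`.
#' @param effect_allele which BIM allele the codes count; `"allele1"`
#'   (default, PLINK A1) or `"allele2"`.
#'
#' @return An object of class `epi_geno`: a list with elements `codes`,
#'   `snps` (tibble), `samples`, `effect_allele`.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3),
#'                  snps = tibble::tibble(snp_id = c("rs1", "rs2"),
#'                                        chr = "1", pos = c(100L, 200L),
#'                                        allele1 = "A", allele2 = "G"))
#' g
geno_matrix <- function(codes, snps, samples = NULL,
                        effect_allele = c("allele1", "allele2")) {
  effect_allele <- match.arg(effect_allele)
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(samples)) {
    samples <- rownames(codes)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  }
  snps <- tibble::as_tibble(snps)
  required <- c("snp_id", "chr", "pos", "allele1", "allele2")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  snps$chr <- as.character(snps$chr)
  snps$pos <- as.integer(snps$pos)
  if (nrow(snps) != ncol(codes)) {
    stop("snps table has ", nrow(snps), " rows but codes has ",
         ncol(codes), " columns")
  }
  if (length(samples) != nrow(codes)) {
    stop("length(samples) != nrow(codes)")
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in panel")
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  if (any(snps$pos <= 0L, na.rm = TRUE)) stop("pos must be > 0")
  if (any(snps$allele1 == snps$allele2)) stop("allele1 must differ from allele2")
  bad <- !(codes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  rownames(codes) <- samples
  colnames(codes) <- snps$snp_id
  structure(
    list(codes = codes, snps = snps, samples = samples,
         effect_allele = effect_allele),
    class = "epi_geno"
  )
}

#' @export
print.epi_geno <- function(x, ...) {
  cat("<epi_geno> ", length(x$samples), " samples x ", nrow(x$snps),
      " SNPs; effect allele = ", x$effect_allele, "\n", sep = "")
  miss <- mean(is.na(x$codes))
  cat("  missing rate: ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.epi_geno <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x an `epi_geno` object.
#' @param i sample selector (indices, logical, or sample IDs).
#' @param j SNP selector (indices, logical, or SNP IDs).
#' @param ... unused.
#' @return An `epi_geno` restricted to the selected samples and SNPs.
#' @export
`[.epi_geno` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  geno_matrix(x$codes[i, j, drop = FALSE],
              snps = x$snps[j, , drop = FALSE],
              samples = x$samples[i],
              effect_allele = x$effect_allele)
}

# Dosage column as double, by index or snp id.
geno_col <- function(x, j) {
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  as.double(x$codes[, j])
}

#' Read a plain-text genotype table
#'
#' A human-readable TSV dialect used mainly for small fixtures: first column
#' `sample_id`, remaining columns one per SNP with values 0/1/2/NA.
#' SNP metadata can be given in a companion table; otherwise placeholder
#' coordinates are generated (chromosome "1", positions 1000, 2000, ...).
#'
#' @param path path to the genotype TSV.
#' @param snp_path optional path to a TSV with columns
#'   `snp_id chr pos allele1 allele2`.
#' @return An [geno_matrix()] object.
#' @export
read_geno_tsv <- function(path, snp_path = NULL) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be sample_id")
  samples <- as.character(tab$sample_id)
  codes <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.null(snp_path)) {
    snps <- utils::read.table(snp_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    snps <- snps[match(colnames(codes), snps$snp_id), , drop = FALSE]
  } else {
    m <- ncol(codes)
    snps <- tibble::tibble(snp_id = colnames(codes), chr = "1",
                           pos = 1000L * seq_len(m),
                           allele1 = "A", allele2 = "B")
  }
  geno_matrix(codes, snps = snps, samples = samples)
}

#' Write the plain-text genotype table dialect
#'
#' @param genotypes an `epi_geno` object.
#' @param path output path for the genotype TSV.
#' @param snp_path optional output path for the SNP metadata TSV.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(genotypes, path, snp_path = NULL) {
  tab <- data.frame(sample_id = genotypes$samples,
                    genotypes$codes, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(snp_path)) {
    utils::write.table(as.data.frame(genotypes$snps), snp_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
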
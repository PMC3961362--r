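# PLINK binary genotype I/O.
#
# BED layout (SNP-major): 3 magic bytes 0x6C 0x1B 0x01, then for each SNP
# ceiling(n/4) bytes, 2 bits per sample, least-significant pair first:
#   00 -> homozygous allele1 (2 copies of the effect allele)
#   01 -> missing
#   10 -> heterozygote
#   11 -> homozygous allele2 (0 copies)

BED_MAGIC <- as.raw(c(0x6C, 0x1B, 0x01))

# bit-pair value (0..3) -> dosage of allele1
.bed_decode_map <- c(2L, NA_integer_, 1L, 0L)
# dosage of allele1 (0,1,2) -> bit-pair value; NA -> 1
.bed_encode_map <- c(3L, 2L, 0L)

#' Read PLINK BED/BIM/FAM files
#'
#' Decodes the SNP-major 2-bit binary genotype format. Codes in the returned
#' matrix count copies of BIM allele 1 (PLINK's A1, conventionally the minor
#' allele); the effect-allele convention is recorded on the object.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. `bim_path` and
#'   `fam_path` default to the `.bed` path with the extension swapped.
#' @return An [geno_matrix()] object.
#' @export
read_plink_bed <- function(bed_path,
                           bim_path = sub("\\.bed$", ".bim", bed_path),
                           fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid",
                                         "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], BED_MAGIC)) {
    if (length(raw) >= 3 && identical(raw[1:2], BED_MAGIC[1:2]) &&
        raw[3] == as.raw(0x00)) {
      stop("BED file is in sample-major mode, which is not supported")
    }
    stop("not a BED file: bad magic bytes in ", bed_path)
  }
  body <- raw[-(1:3)]
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m) {
    stop("truncated or oversized BED stream: expected ",
         bytes_per_snp * m, " body bytes, found ", length(body))
  }
  q <- as.integer(body)
  dim(q) <- c(bytes_per_snp, m)
  # expand each byte into its 4 bit-pairs (sample index runs fastest)
  pairs <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
  for (k in 0:3) {
    pairs[seq.int(k + 1L, by = 4L, length.out = bytes_per_snp), ] <-
      (q %/% (4L^k)) %% 4L
  }
  codes <- .bed_decode_map[pairs[seq_len(n), , drop = FALSE] + 1L]
  dim(codes) <- c(n, m)
  snps <- tibble::tibble(snp_id = bim$snp_id, chr = bim$chr, pos = bim$pos,
                         allele1 = bim$allele1, allele2 = bim$allele2)
  geno_matrix(codes, snps = snps, samples = as.character(fam$iid))
}

#' Write PLINK BED/BIM/FAM files
#'
#' Inverse of [read_plink_bed()]; writes SNP-major BED with padding bits set
#' to zero, a 6-column BIM and a 6-column FAM (FID = IID, unknown parents,
#' sex 0, phenotype -9).
#'
#' @param genotypes an `epi_geno` object.
#' @param prefix output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return The prefix, invisibly.
#' @export
write_plink_bed <- function(genotypes, prefix) {
  codes <- genotypes$codes
  n <- nrow(codes)
  m <- ncol(codes)
  bytes_per_snp <- ceiling(n / 4)
  enc <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
  vals <- ifelse(is.na(codes), 1L, .bed_encode_map[codes + 1L])
  enc[seq_len(n), ] <- vals
  body <- integer(bytes_per_snp * m)
  dim(body) <- c(bytes_per_snp, m)
  for (k in 0:3) {
    body <- body +
      enc[seq.int(k + 1L, by = 4L, length.out = bytes_per_snp), ,
          drop = FALSE] * (4L^k)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(body), con)
  snps <- genotypes$snps
  bim <- data.frame(snps$chr, snps$snp_id, 0, snps$pos,
                    snps$allele1, snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(genotypes$samples, genotypes$samples, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
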
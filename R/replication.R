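# Locus-based replication of a discovered interaction in an independent
# cohort: any SNP pair across windows around the two discovery loci counts.

#' Specify a locus-based replication attempt
#'
#' @param snp1_id,snp2_id IDs of the discovery pair.
#' @param chr1,pos1,chr2,pos2 coordinates of the discovery pair (used to
#'   define the two locus windows in the replication panel).
#' @param window_kb half-width of each locus window in kb per side.
#' @param alpha significance level applied to the Bonferroni-corrected best
#'   P value for declaring replication.
#' @param trait,covariates column names used in the replication cohort.
#' @return A list of class `epi_replication_spec`.
#' @export
replication_spec <- function(snp1_id, snp2_id, chr1, pos1, chr2, pos2,
                             window_kb = 100, alpha = 0.05,
                             trait = "trait",
                             covariates = c("age", "sex", "bmi")) {
  stopifnot(window_kb > 0, alpha > 0, alpha <= 1)
  structure(
    list(snp1_id = snp1_id, snp2_id = snp2_id,
         chr1 = as.character(chr1), pos1 = as.integer(pos1),
         chr2 = as.character(chr2), pos2 = as.integer(pos2),
         window_kb = window_kb, alpha = alpha,
         trait = trait, covariates = covariates),
    class = "epi_replication_spec"
  )
}

#' Locus-based replication test
#'
#' Enumerates every cross-locus pair (one SNP from the window around each
#' discovery locus, never two from the same window), applies the minimum
#' cell-count filter, runs the interaction F-test, and Bonferroni-corrects
#' the best P value for the number of cross-locus pairs actually tested.
#' Replication is declared when the corrected P value is below
#' `spec$alpha`. The result is invariant to swapping the two loci in the
#' spec.
#'
#' @param spec a [replication_spec()].
#' @param genotypes replication-panel `epi_geno` (QC already applied).
#' @param cohort replication cohort tibble.
#' @param min_cell minimum genotype cell count per tested pair.
#' @return A list of class `epi_replication`: `results` (tibble of tested
#'   cross-locus pairs), `best` (one-row tibble), `bonferroni_m`,
#'   `corrected_p`, `replicated`, and the window memberships.
#' @export
locus_replicate <- function(spec, genotypes, cohort, min_cell = 10) {
  snps <- genotypes$snps
  half_bp <- spec$window_kb * 1000
  w1 <- which(snps$chr == spec$chr1 & abs(snps$pos - spec$pos1) <= half_bp)
  w2 <- which(snps$chr == spec$chr2 & abs(snps$pos - spec$pos2) <= half_bp)
  if (length(w1) == 0) {
    stop("no replication-panel SNPs in the window around locus 1 (",
         spec$snp1_id, ")")
  }
  if (length(w2) == 0) {
    stop("no replication-panel SNPs in the window around locus 2 (",
         spec$snp2_id, ")")
  }
  pair_idx <- as.matrix(expand.grid(i = w1, j = w2))
  pair_idx <- pair_idx[pair_idx[, 1] != pair_idx[, 2], , drop = FALSE]
  # canonical orientation so (i, j) and (j, i) never both appear when the
  # windows overlap
  flip <- pair_idx[, 1] > pair_idx[, 2]
  pair_idx[flip, ] <- pair_idx[flip, c(2, 1)]
  pair_idx <- unique(pair_idx)
  scan <- .scan_pairs(genotypes, cohort, pair_idx,
                      trait = spec$trait, covariates = spec$covariates,
                      min_cell = min_cell, fdr_q = 0.25,
                      coding = "additive_dominance")
  res <- scan$results
  m <- scan$n_pairs_tested
  if (m > 0) {
    best <- res[1, , drop = FALSE]
    corrected_p <- bonferroni_adjust(best$p, m)
  } else {
    best <- res
    corrected_p <- NA_real_
  }
  structure(
    list(results = res, best = best, bonferroni_m = m,
         corrected_p = corrected_p,
         replicated = isTRUE(corrected_p < spec$alpha),
         locus1_snps = snps$snp_id[w1], locus2_snps = snps$snp_id[w2],
         spec = spec),
    class = "epi_replication"
  )
}

#' @export
print.epi_replication <- function(x, ...) {
  cat("<epi_replication> loci around ", x$spec$snp1_id, " / ",
      x$spec$snp2_id, " (+/- ", x$spec$window_kb, " kb)\n", sep = "")
  cat("  cross-locus pairs tested:", x$bonferroni_m, "\n")
  if (x$bonferroni_m > 0) {
    cat(sprintf("  best pair %s x %s: p = %.3g, corrected p = %.3g\n",
                x$best$snp1, x$best$snp2, x$best$p, x$corrected_p))
  }
  cat("  replicated at alpha =", x$spec$alpha, ":", x$replicated, "\n")
  invisible(x)
}
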
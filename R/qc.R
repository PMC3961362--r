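# Sample/SNP quality control: call rates and exact Hardy-Weinberg test.

#' Per-sample genotype call rate
#'
#' @param genotypes an `epi_geno` object.
#' @return Named numeric vector in `[0, 1]`: fraction of non-missing SNP
#'   calls per sample.
#' @export
sample_call_rate <- function(genotypes) {
  if (ncol(genotypes$codes) == 0) stop("genotype matrix has zero SNPs")
  r <- rowMeans(!is.na(genotypes$codes))
  names(r) <- genotypes$samples
  r
}

#' Per-SNP genotype call rate
#'
#' @param genotypes an `epi_geno` object.
#' @return Named numeric vector in `[0, 1]`.
#' @export
snp_call_rate <- function(genotypes) {
  if (nrow(genotypes$codes) == 0) stop("genotype matrix has zero samples")
  r <- colMeans(!is.na(genotypes$codes))
  names(r) <- genotypes$snps$snp_id
  r
}

# Probability mass over heterozygote counts conditional on n diploids and
# m copies of the rare allele, computed by the stable ratio recurrence:
#   P(h + 2) / P(h) = 4 * n_hom_rare(h) * n_hom_common(h) / ((h + 2)(h + 1))
# Returns list(het = attainable het counts, pmf = probabilities).
.hwe_het_pmf <- function(n, m) {
  stopifnot(m <= n)              # m is the rare-allele count, m <= 2n - m
  het <- seq.int(m %% 2L, min(m, 2L * n - m), by = 2L)
  k <- length(het)
  u <- numeric(k)
  # start at the modal het count for numerical headroom
  mid_val <- round(m * (2 * n - m) / (2 * n))
  start <- which.min(abs(het - mid_val))
  u[start] <- 1
  if (start < k) {
    for (i in start:(k - 1L)) {
      h <- het[i]
      hom_r <- (m - h) / 2
      hom_c <- n - h - hom_r
      u[i + 1L] <- u[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (start > 1L) {
    for (i in start:2L) {
      h <- het[i]
      hom_r <- (m - h) / 2 + 1
      hom_c <- n - (h - 2) - hom_r
      # inverse of the upward ratio evaluated at h - 2
      u[i - 1L] <- u[i] * h * (h - 1) / (4 * hom_r * hom_c)
    }
  }
  list(het = het, pmf = u / sum(u))
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed allele counts with the standard
#' probability-mass ordering: the P value is the total probability of all
#' heterozygote counts whose probability does not exceed that of the observed
#' one. Two-sided by construction.
#'
#' @param n_hom1,n_het,n_hom2 non-negative genotype counts (homozygote for
#'   allele 1, heterozygote, homozygote for allele 2).
#' @return P value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  m <- min(2 * n_hom1 + n_het, 2 * n_hom2 + n_het)  # rare allele copies
  d <- .hwe_het_pmf(n, m)
  obs <- which(d$het == n_het)
  p_obs <- d$pmf[obs]
  min(1, sum(d$pmf[d$pmf <= p_obs * (1 + 1e-12)]))
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit alternative to the exact test,
#' exposed as an option for large counts.
#'
#' @inheritParams hwe_exact_test
#' @return P value.
#' @export
hwe_chisq_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * n_hom1 + n_het) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_hom1, n_het, n_hom2) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

.snp_hwe_p <- function(col) {
  g <- col[!is.na(col)]
  tab <- tabulate(g + 1L, nbins = 3L)
  if (sum(tab) == 0) return(NA_real_)
  hwe_exact_test(tab[3], tab[2], tab[1])  # hom for allele coded 2 vs 0
}

#' Apply call-rate and Hardy-Weinberg quality control
#'
#' Filter order is fixed: (1) samples with call rate below `sample_cr_min`
#' are removed; (2) SNPs with call rate below `snp_cr_min`, computed on the
#' retained samples, are removed; (3) SNPs with exact Hardy-Weinberg P below
#' `hwe_alpha`, computed on the retained samples, are removed. All
#' comparisons are strict (`<`), so a sample at exactly the threshold is
#' retained.
#'
#' @param genotypes an `epi_geno` object.
#' @param sample_cr_min,snp_cr_min minimum call rates in `(0, 1]`.
#' @param hwe_alpha Hardy-Weinberg significance threshold.
#' @return A list with `genotypes` (the filtered `epi_geno`) and `report`,
#'   a list with tibbles `samples_removed` (`sample_id`, `call_rate`) and
#'   `snps_removed` (`snp_id`, `reason` in `{call_rate, hwe}`, `value`), plus
#'   the thresholds used.
#' @export
apply_qc <- function(genotypes, sample_cr_min = 0.90, snp_cr_min = 0.90,
                     hwe_alpha = 0.001) {
  stopifnot(sample_cr_min > 0, sample_cr_min <= 1,
            snp_cr_min > 0, snp_cr_min <= 1)
  scr <- sample_call_rate(genotypes)
  bad_samples <- scr < sample_cr_min
  samples_removed <- tibble::tibble(sample_id = genotypes$samples[bad_samples],
                                    call_rate = unname(scr[bad_samples]))
  if (all(bad_samples)) {
    err <- simpleError("all samples removed by the call-rate filter")
    err$report <- samples_removed
    stop(err)
  }
  g <- genotypes[!bad_samples, ]

  ccr <- snp_call_rate(g)
  bad_cr <- ccr < snp_cr_min
  hwe_p <- rep(NA_real_, ncol(g$codes))
  keep_idx <- which(!bad_cr)
  hwe_p[keep_idx] <- apply(g$codes[, keep_idx, drop = FALSE], 2, .snp_hwe_p)
  bad_hwe <- !bad_cr & !is.na(hwe_p) & hwe_p < hwe_alpha

  snps_removed <- tibble::tibble(
    snp_id = c(g$snps$snp_id[bad_cr], g$snps$snp_id[bad_hwe]),
    reason = c(rep("call_rate", sum(bad_cr)), rep("hwe", sum(bad_hwe))),
    value = c(unname(ccr[bad_cr]), hwe_p[bad_hwe])
  )
  g <- g[, !(bad_cr | bad_hwe)]
  list(
    genotypes = g,
    report = list(samples_removed = samples_removed,
                  snps_removed = snps_removed,
                  thresholds = c(sample_cr_min = sample_cr_min,
                                 snp_cr_min = snp_cr_min,
                                 hwe_alpha = hwe_alpha))
  )
}

#' Write a QC report as TSV
#'
#' @param report the `report` element returned by [apply_qc()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- report$thresholds
  writeLines(paste0("# ", names(th), ": ", th), con)
  writeLines("id\ttype\treason\tvalue", con)
  sr <- report$samples_removed
  if (nrow(sr) > 0) {
    writeLines(paste(sr$sample_id, "sample", "call_rate",
                     .format_num(sr$call_rate), sep = "\t"), con)
  }
  mr <- report$snps_removed
  if (nrow(mr) > 0) {
    writeLines(paste(mr$snp_id, "snp", mr$reason,
                     .format_num(mr$value), sep = "\t"), con)
  }
  invisible(path)
}
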
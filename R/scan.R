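# All-pairs and single-anchor ("hub") interaction scans with pair filtering,
# multiplicity correction and QQ export.

#' Minimum genotype-cell-count pair filter
#'
#' Counts the nine genotype combinations of a SNP pair on the complete-case
#' subset. The pair passes only when the least frequent of the nine
#' combinations is carried by at least `min_count` individuals; an empty cell
#' always fails. The boundary is inclusive: a cell of exactly `min_count`
#' passes.
#'
#' @param g1,g2 dosage vectors.
#' @param min_count minimum count for the rarest combination.
#' @return A list with `pass` (logical) and `cell_counts` (3x3 integer
#'   matrix).
#' @export
min_cell_filter <- function(g1, g2, min_count = 10) {
  cells <- genotype_cell_counts(g1, g2)
  list(pass = min(cells) >= min_count, cell_counts = cells)
}

#' Bonferroni adjustment
#'
#' @param p raw P value(s) in `(0, 1]`.
#' @param m number of tests; must be at least 1.
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (length(m) != 1 || m < 1) stop("m must be a single count >= 1")
  pmin(1, p * m)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure. Q-values are the usual monotone-adjusted
#' values (via [stats::p.adjust()]); the rejection set is every P value whose
#' q-value is at most `q`.
#'
#' @param p_list raw P values.
#' @param q target FDR level.
#' @return A list with logical `reject` and numeric `q_values`, both aligned
#'   with `p_list`; empty input gives empty outputs.
#' @export
bh_fdr <- function(p_list, q = 0.25) {
  if (length(p_list) == 0) {
    return(list(reject = logical(0), q_values = numeric(0)))
  }
  qv <- stats::p.adjust(p_list, method = "BH")
  list(reject = qv <= q, q_values = qv)
}

#' Expected-vs-observed quantiles for a QQ plot
#'
#' Observed P values are sorted ascending and paired with the uniform
#' order-statistic expectations i/(m+1); both are returned on the -log10
#' scale. Zero P values are clamped to the smallest positive double and
#' flagged with a warning.
#'
#' @param p_list non-empty vector of P values.
#' @return A tibble with columns `expected` and `observed` (-log10 scale).
#' @export
qq_points <- function(p_list) {
  if (length(p_list) == 0) stop("empty P value list")
  if (any(p_list == 0, na.rm = TRUE)) {
    warning("P values of 0 clamped to the smallest positive double")
    p_list[p_list == 0] <- .Machine$double.xmin
  }
  p <- sort(p_list[!is.na(p_list)])
  m <- length(p)
  tibble::tibble(expected = -log10(seq_len(m) / (m + 1)),
                 observed = -log10(p))
}

# Align genotypes with the cohort table: samples present in both with
# complete trait and covariates. Returns y, covariate matrix Z, and the
# epi_geno restricted to those samples.
.align_cohort <- function(genotypes, cohort, trait, covariates) {
  if (!trait %in% names(cohort)) stop("trait column '", trait, "' not in cohort")
  miss_cov <- setdiff(covariates, names(cohort))
  if (length(miss_cov) > 0) {
    stop("covariate column(s) not in cohort: ", paste(miss_cov, collapse = ", "))
  }
  idx <- match(genotypes$samples, cohort$sample_id)
  keep <- !is.na(idx)
  sub <- cohort[idx[keep], , drop = FALSE]
  ok <- !is.na(sub[[trait]])
  if (length(covariates) > 0) {
    ok <- ok & stats::complete.cases(sub[, covariates, drop = FALSE])
  }
  g <- genotypes[which(keep)[ok], ]
  sub <- sub[ok, , drop = FALSE]
  Z <- if (length(covariates) > 0) {
    as.matrix(sub[, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(sub), ncol = 0)
  }
  storage.mode(Z) <- "double"
  list(genotypes = g, y = as.double(sub[[trait]]), Z = Z)
}

# Fast per-pair engine for fully observed genotype columns. Residualizes the
# genotype-derived columns against the covariate design (Frisch-Waugh-Lovell)
# using a QR computed once; returns the same statistics as
# interaction_f_test().
.pair_engine_fast <- function(env, i, j) {
  x1 <- env$x[, i]; z1 <- env$z[, i]
  x2 <- env$x[, j]; z2 <- env$z[, j]
  M <- cbind(x1, z1, x2, z2,
             x1 * x2, x1 * z2, z1 * x2, z1 * z2)
  RM <- M - env$Q %*% crossprod(env$Q, M)
  qm <- qr(RM[, 1:4, drop = FALSE], tol = 1e-9)
  rss_m <- sum(qr.resid(qm, env$ry)^2)
  qf <- qr(RM, tol = 1e-9)
  rss_f <- sum(qr.resid(qf, env$ry)^2)
  qdf <- qf$rank - qm$rank
  rank_f <- env$rank_c + qf$rank
  df_den <- env$n - rank_f
  if (qdf == 0 || df_den <= 0) return(NULL)
  Fstat <- ((rss_m - rss_f) / qdf) / (rss_f / df_den)
  qs <- qr(RM[, 1:2, drop = FALSE], tol = 1e-9)
  rss_s <- sum(qr.resid(qs, env$ry)^2)
  list(F = Fstat, df_num = qdf, df_den = df_den,
       p = min(1, stats::pf(Fstat, qdf, df_den, lower.tail = FALSE)),
       r2_marginal = 1 - rss_m / env$tss,
       r2_full = 1 - rss_f / env$tss,
       delta_r2 = max(0, (rss_m - rss_f) / env$tss),
       delta_r2_vs_single = (rss_s - rss_f) / env$tss)
}

# Core scan over an explicit pair index matrix. Pairs with missing genotype
# entries fall back to the one-pair episcore path so both routes share
# complete-case semantics.
.scan_pairs <- function(genotypes, cohort, pair_idx, trait, covariates,
                        min_cell, fdr_q, coding) {
  al <- .align_cohort(genotypes, cohort, trait, covariates)
  g <- al$genotypes
  n <- length(al$y)
  if (n == 0) stop("no samples with complete trait and covariates")
  C <- cbind(rep(1, n), al$Z)
  qc_ <- qr(C, tol = 1e-9)
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$rank_c <- qc_$rank
  env$Q <- qr.Q(qc_)[, seq_len(qc_$rank), drop = FALSE]
  env$ry <- al$y - env$Q %*% crossprod(env$Q, al$y)
  env$tss <- sum((al$y - mean(al$y))^2)

  codes <- g$codes
  has_na <- colSums(is.na(codes)) > 0L
  if (coding == "additive_dominance") {
    env$x <- matrix(as.double(codes), nrow = n)
    env$z <- (env$x == 1) * 1.0
  } else {
    env$x <- matrix(as.double(codes), nrow = n) - 1
    env$z <- ifelse(env$x == 0, 0.5, -0.5)
  }

  np <- nrow(pair_idx)
  out <- vector("list", np)
  n_tested <- 0L
  n_filtered <- 0L
  n_untestable <- 0L
  snps <- g$snps
  for (k in seq_len(np)) {
    i <- pair_idx[k, 1]
    j <- pair_idx[k, 2]
    if (has_na[i] || has_na[j]) {
      g1 <- as.double(codes[, i]); g2 <- as.double(codes[, j])
      ok <- !is.na(g1) & !is.na(g2)
      cells <- genotype_cell_counts(g1[ok], g2[ok])
      if (min(cells) < min_cell) { n_filtered <- n_filtered + 1L; next }
      ft <- interaction_f_test(al$y, al$Z, g1, g2, coding = coding,
                               snp1_id = snps$snp_id[i],
                               snp2_id = snps$snp_id[j])
      if (!isTRUE(ft$testable)) { n_untestable <- n_untestable + 1L; next }
      row <- list(F = ft$F, df_num = ft$df_num, df_den = ft$df_den, p = ft$p,
                  r2_marginal = ft$r2_marginal, r2_full = ft$r2_full,
                  delta_r2 = ft$delta_r2,
                  delta_r2_vs_single = ft$delta_r2_vs_single)
      n_used <- ft$n_used
      mcc <- min(ft$cell_counts)
    } else {
      cells <- genotype_cell_counts(codes[, i], codes[, j])
      if (min(cells) < min_cell) { n_filtered <- n_filtered + 1L; next }
      row <- .pair_engine_fast(env, i, j)
      if (is.null(row)) { n_untestable <- n_untestable + 1L; next }
      n_used <- n
      mcc <- min(cells)
    }
    n_tested <- n_tested + 1L
    out[[k]] <- tibble::tibble(
      snp1 = snps$snp_id[i], snp2 = snps$snp_id[j],
      chr1 = snps$chr[i], chr2 = snps$chr[j],
      pos1 = snps$pos[i], pos2 = snps$pos[j],
      n_used = n_used, F = row$F, df1 = row$df_num, df2 = row$df_den,
      p = row$p, r2_marginal = row$r2_marginal, r2_full = row$r2_full,
      delta_r2 = row$delta_r2,
      delta_r2_vs_single = row$delta_r2_vs_single,
      min_cell_count = as.integer(mcc))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    res$p_bonferroni <- bonferroni_adjust(res$p, max(1L, n_tested))
    fdr <- bh_fdr(res$p, fdr_q)
    res$q_bh <- fdr$q_values
    res$significant_fdr <- fdr$reject
    res <- res[order(res$p, res$snp1, res$snp2), , drop = FALSE]
    res <- res[, c(RESULT_COLUMNS, "significant_fdr"), drop = FALSE]
  }
  structure(
    list(results = res,
         n_pairs_enumerated = np,
         n_pairs_filtered = n_filtered,
         n_pairs_untestable = n_untestable,
         n_pairs_tested = n_tested,
         bonferroni_m = n_tested,
         fdr_q = fdr_q,
         n_samples = n,
         min_cell = min_cell),
    class = "epi_scan"
  )
}

#' All-pairs SNP-SNP interaction scan
#'
#' Enumerates every unordered pair of SNPs, applies the minimum
#' genotype-cell-count filter, runs the 4-df interaction F-test on the
#' passing pairs, and corrects for multiplicity: Bonferroni over the number
#' of pairs actually tested (not pairs enumerated) and Benjamini-Hochberg
#' q-values. QC should already have been applied.
#'
#' @param genotypes an `epi_geno` object (at least 2 SNPs).
#' @param cohort cohort tibble with `sample_id`, the trait, and covariates.
#' @param trait name of the trait column.
#' @param covariates names of the covariate columns.
#' @param min_cell minimum count for the rarest of the 9 genotype cells.
#' @param fdr_q Benjamini-Hochberg FDR level for the `significant_fdr` flag.
#' @param coding genotype coding, see [encode_genotype()].
#' @return An object of class `epi_scan`: a list with `results` (tibble, one
#'   row per tested pair, sorted by p), the multiplicity ledger
#'   (`n_pairs_enumerated`, `n_pairs_filtered`, `n_pairs_untestable`,
#'   `n_pairs_tested`, `bonferroni_m`), and settings.
#' @export
all_pairs_scan <- function(genotypes, cohort, trait = "trait",
                           covariates = c("age", "sex", "bmi"),
                           min_cell = 10, fdr_q = 0.25,
                           coding = "additive_dominance") {
  m <- nrow(genotypes$snps)
  if (m < 2) stop("need at least 2 SNPs for an all-pairs scan")
  pair_idx <- t(utils::combn(m, 2))
  .scan_pairs(genotypes, cohort, pair_idx, trait, covariates,
              min_cell, fdr_q, coding)
}

#' Single-anchor ("hub") interaction scan
#'
#' Tests the anchor SNP against every other SNP in the panel (typically an
#' LD-pruned panel) with the same pair filter, test and corrections as
#' [all_pairs_scan()]. Partners within `near_anchor_kb` of the anchor on the
#' same chromosome are flagged in the `near_anchor` column but not excluded.
#'
#' @inheritParams all_pairs_scan
#' @param anchor SNP ID of the anchor; it becomes `snp1` of every pair.
#' @param near_anchor_kb proximity flag distance in kb (default 1000 = 1 Mb).
#' @return An `epi_scan` object; see [all_pairs_scan()].
#' @export
hub_scan <- function(genotypes, cohort, anchor, trait = "trait",
                     covariates = c("age", "sex", "bmi"),
                     min_cell = 10, fdr_q = 0.25,
                     coding = "additive_dominance", near_anchor_kb = 1000) {
  a <- match(anchor, genotypes$snps$snp_id)
  if (is.na(a)) stop("anchor SNP '", anchor, "' not in panel")
  ga <- genotypes$codes[, a]
  if (length(unique(ga[!is.na(ga)])) < 2) {
    stop("anchor SNP '", anchor, "' is monomorphic")
  }
  partners <- setdiff(seq_len(nrow(genotypes$snps)), a)
  if (length(partners) == 0) {
    pair_idx <- matrix(integer(0), ncol = 2)
  } else {
    pair_idx <- cbind(a, partners)
  }
  scan <- .scan_pairs(genotypes, cohort, pair_idx, trait, covariates,
                      min_cell, fdr_q, coding)
  scan$anchor <- anchor
  if (nrow(scan$results) > 0) {
    snps <- genotypes$snps
    achr <- snps$chr[a]
    apos <- snps$pos[a]
    scan$results$near_anchor <- scan$results$chr2 == achr &
      abs(scan$results$pos2 - apos) <= near_anchor_kb * 1000
  }
  scan
}

#' @export
print.epi_scan <- function(x, ...) {
  cat("<epi_scan>", if (!is.null(x$anchor)) paste0("anchor = ", x$anchor),
      "\n")
  cat("  pairs: ", x$n_pairs_enumerated, " enumerated, ",
      x$n_pairs_filtered, " filtered, ", x$n_pairs_untestable,
      " untestable, ", x$n_pairs_tested, " tested\n", sep = "")
  if (nrow(x$results) > 0) {
    top <- x$results[1, ]
    cat(sprintf("  top pair: %s x %s, p = %.3g (Bonferroni %.3g, q = %.3g)\n",
                top$snp1, top$snp2, top$p, top$p_bonferroni, top$q_bh))
    cat("  significant at FDR", x$fdr_q, ":",
        sum(x$results$significant_fdr), "\n")
  }
  invisible(x)
}

#' Export QQ points of a scan to TSV
#'
#' @param scan an `epi_scan` object.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_qq <- function(scan, path) {
  qq <- qq_points(scan$results$p)
  utils::write.table(format(as.data.frame(qq), digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
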
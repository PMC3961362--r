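# The interaction test: genotype coding, nested linear models, 4-df F-test,
# and variance-explained decomposition.

#' Encode a genotype dosage vector as additive + dominance columns
#'
#' The default coding is x = dosage (0/1/2) and z = heterozygote indicator
#' (0/1/0). The alternative "cordell" coding uses x in \{-1, 0, 1\} and
#' z in \{-0.5, 0.5, -0.5\}. Any full-rank coding pair spans the same column
#' space over the three genotype classes, so the interaction F-test is
#' invariant to this choice. Missing dosages propagate as `NA`.
#'
#' @param g dosage vector with values in `{0, 1, 2, NA}`.
#' @param coding `"additive_dominance"` (default) or `"cordell"`.
#' @return A list of class `epi_coding` with elements `x`, `z`, `coding_name`.
#' @export
#' @examples
#' encode_genotype(c(0, 1, 2))
encode_genotype <- function(g, coding = c("additive_dominance", "cordell")) {
  coding <- match.arg(coding)
  g <- as.double(g)
  if (any(!(g %in% c(0, 1, 2)) & !is.na(g))) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (coding == "additive_dominance") {
    x <- g
    z <- as.double(g == 1)
  } else {
    x <- g - 1
    z <- ifelse(g == 1, 0.5, -0.5)
  }
  z[is.na(g)] <- NA_real_
  structure(list(x = x, z = z, coding_name = coding), class = "epi_coding")
}

# Rank-revealing least squares on a prepared design matrix. Returns RSS,
# rank, and pivoted coefficients (NA for aliased columns).
.fit_rss <- function(y, X, tol = 1e-9, want_coef = FALSE) {
  qx <- qr(X, tol = tol)
  res <- qr.resid(qx, y)
  out <- list(rss = sum(res^2), rank = qx$rank)
  if (want_coef) out$coefficients <- qr.coef(qx, y)
  out
}

.as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  Z <- as.matrix(as.data.frame(covariates))
  storage.mode(Z) <- "double"
  if (nrow(Z) != n) stop("covariates and y differ in length")
  Z
}

#' Least-squares fit with rank handling
#'
#' Fits `y` on the given design columns (an intercept is *not* added
#' automatically) by a rank-revealing QR decomposition; rank-deficient
#' designs are fitted on an identified full-rank column subset with aliased
#' coefficients reported as `NA`.
#'
#' @param y numeric response; complete cases only.
#' @param X numeric design matrix.
#' @return A list of class `epi_lm`: `coefficients`, `rss`, `rank`, `n_used`,
#'   `df_residual`, `r_squared` (about-the-mean definition).
#' @export
fit_linear <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (anyNA(y) || anyNA(X)) stop("fit_linear expects complete cases")
  if (length(y) == 0) stop("empty response")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance")
  f <- .fit_rss(y, X, want_coef = TRUE)
  structure(
    list(coefficients = f$coefficients, rss = f$rss, rank = f$rank,
         n_used = length(y), df_residual = length(y) - f$rank,
         r_squared = 1 - f$rss / tss),
    class = "epi_lm"
  )
}

#' @export
print.epi_lm <- function(x, ...) {
  cat("<epi_lm> n =", x$n_used, " rank =", x$rank,
      " R2 =", signif(x$r_squared, 4), "\n")
  invisible(x)
}

# 3x3 genotype combination counts (rows: g1 = 0,1,2; cols: g2 = 0,1,2)
genotype_cell_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  counts <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
  matrix(counts, nrow = 3, byrow = TRUE,
         dimnames = list(g1 = 0:2, g2 = 0:2))
}

.untestable <- function(snp1_id, snp2_id, n_used, cell_counts, reason) {
  structure(
    list(snp1_id = snp1_id, snp2_id = snp2_id, n_used = n_used,
         F = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
         p = NA_real_, r2_marginal = NA_real_, r2_full = NA_real_,
         delta_r2 = NA_real_, delta_r2_vs_single = NA_real_,
         cell_counts = cell_counts, testable = FALSE, reason = reason),
    class = "epi_pair_test"
  )
}

#' Four-degree-of-freedom test for pure SNP-SNP interaction
#'
#' Fits two nested linear models on the complete-case subset:
#' the marginal model
#' `y ~ covariates + a1*x1 + d1*z1 + a2*x2 + d2*z2`
#' and the full model adding the four interaction terms
#' `i_aa*x1*x2 + i_ad*x1*z2 + i_da*z1*x2 + i_dd*z1*z2`,
#' then compares them with an F-test. The numerator degrees of freedom are
#' the realized rank difference q (4 when all nine genotype cells are
#' populated, fewer when cells are empty); the test is therefore for
#' interaction effects on top of, and beyond, any marginal effect of either
#' SNP. When the interaction columns add no rank (q = 0) the pair is flagged
#' untestable rather than assigned p = 1.
#'
#' @param y numeric trait vector.
#' @param covariates data frame or matrix of covariates (may be `NULL`).
#' @param g1,g2 dosage vectors for the two SNPs.
#' @param coding genotype coding passed to [encode_genotype()].
#' @param snp1_id,snp2_id labels carried into the result; `snp1` is the
#'   designated anchor for `delta_r2_vs_single`.
#' @return A list of class `epi_pair_test`: F statistic, numerator and
#'   denominator df, p, R-squared of both models, `delta_r2`
#'   (= r2_full - r2_marginal), `delta_r2_vs_single` (r2_full minus the
#'   R-squared of the intercept + covariates + anchor-SNP model), the 3x3
#'   genotype `cell_counts`, `n_used`, and a `testable` flag.
#' @export
interaction_f_test <- function(y, covariates = NULL, g1, g2,
                               coding = "additive_dominance",
                               snp1_id = "snp1", snp2_id = "snp2") {
  y <- as.double(y)
  Z <- .as_covariate_matrix(covariates, length(y))
  g1 <- as.double(g1)
  g2 <- as.double(g2)
  if (length(g1) != length(y) || length(g2) != length(y)) {
    stop("y, g1 and g2 must have equal length")
  }
  cc <- !is.na(y) & !is.na(g1) & !is.na(g2)
  if (ncol(Z) > 0) cc <- cc & stats::complete.cases(Z)
  y <- y[cc]; g1 <- g1[cc]; g2 <- g2[cc]
  Z <- Z[cc, , drop = FALSE]
  n <- length(y)
  cells <- genotype_cell_counts(g1, g2)
  if (n == 0 || length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    return(.untestable(snp1_id, snp2_id, n, cells, "monomorphic"))
  }
  e1 <- encode_genotype(g1, coding)
  e2 <- encode_genotype(g2, coding)
  C <- cbind(`(Intercept)` = rep(1, n), Z)
  Xm <- cbind(C, a1 = e1$x, d1 = e1$z, a2 = e2$x, d2 = e2$z)
  Xf <- cbind(Xm, i_aa = e1$x * e2$x, i_ad = e1$x * e2$z,
              i_da = e1$z * e2$x, i_dd = e1$z * e2$z)
  fm <- .fit_rss(y, Xm)
  ff <- .fit_rss(y, Xf, want_coef = TRUE)
  q <- ff$rank - fm$rank
  if (q == 0) {
    return(.untestable(snp1_id, snp2_id, n, cells, "collinear_interaction"))
  }
  df_den <- n - ff$rank
  if (df_den <= 0) {
    return(.untestable(snp1_id, snp2_id, n, cells, "saturated"))
  }
  tss <- sum((y - mean(y))^2)
  Fstat <- ((fm$rss - ff$rss) / q) / (ff$rss / df_den)
  p <- min(1, stats::pf(Fstat, q, df_den, lower.tail = FALSE))
  fs <- .fit_rss(y, cbind(C, a1 = e1$x, d1 = e1$z))
  structure(
    list(snp1_id = snp1_id, snp2_id = snp2_id, n_used = n,
         F = Fstat, df_num = q, df_den = df_den, p = p,
         r2_marginal = 1 - fm$rss / tss,
         r2_full = 1 - ff$rss / tss,
         delta_r2 = max(0, (fm$rss - ff$rss) / tss),
         delta_r2_vs_single = (fs$rss - ff$rss) / tss,
         cell_counts = cells,
         coefficients = ff$coefficients,
         testable = TRUE, reason = NA_character_),
    class = "epi_pair_test"
  )
}

#' @export
print.epi_pair_test <- function(x, ...) {
  cat("<epi_pair_test> ", x$snp1_id, " x ", x$snp2_id,
      " (n = ", x$n_used, ")\n", sep = "")
  if (isTRUE(x$testable)) {
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df_num, x$df_den, x$F, x$p))
    cat(sprintf("  R2 marginal = %.4g, full = %.4g, delta = %.4g\n",
                x$r2_marginal, x$r2_full, x$delta_r2))
  } else {
    cat("  untestable:", x$reason, "\n")
  }
  invisible(x)
}

#' Trait variance attributable to one SNP
#'
#' The R-squared increment of `intercept + covariates + a*x + d*z` over
#' `intercept + covariates`, i.e. the fraction of trait variance explained
#' by the SNP beyond the covariates. A SNP monomorphic on the complete-case
#' subset contributes a 0 increment, flagged via the `"monomorphic"`
#' attribute.
#'
#' @inheritParams interaction_f_test
#' @param g dosage vector.
#' @return The R-squared increment, with attribute `monomorphic`.
#' @export
single_snp_r2 <- function(y, covariates = NULL, g,
                          coding = "additive_dominance") {
  y <- as.double(y)
  Z <- .as_covariate_matrix(covariates, length(y))
  g <- as.double(g)
  cc <- !is.na(y) & !is.na(g)
  if (ncol(Z) > 0) cc <- cc & stats::complete.cases(Z)
  y <- y[cc]; g <- g[cc]
  Z <- Z[cc, , drop = FALSE]
  if (length(unique(g)) < 2) {
    return(structure(0, monomorphic = TRUE))
  }
  e <- encode_genotype(g, coding)
  C <- cbind(1, Z)
  tss <- sum((y - mean(y))^2)
  f0 <- .fit_rss(y, C)
  f1 <- .fit_rss(y, cbind(C, e$x, e$z))
  structure(max(0, (f0$rss - f1$rss) / tss), monomorphic = FALSE)
}
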
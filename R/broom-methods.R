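# tidy()/glance() methods so fitted objects drop into dplyr workflows.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.epi_scan
#' @method tidy epi_pair_test
#' @export
tidy.epi_pair_test <- function(x, ...) {
  tibble::tibble(
    snp1 = x$snp1_id, snp2 = x$snp2_id, n_used = x$n_used,
    F = x$F, df1 = x$df_num, df2 = x$df_den, p = x$p,
    r2_marginal = x$r2_marginal, r2_full = x$r2_full,
    delta_r2 = x$delta_r2, delta_r2_vs_single = x$delta_r2_vs_single,
    min_cell_count = as.integer(min(x$cell_counts)),
    testable = isTRUE(x$testable))
}

#' Tidy and summarize scan objects
#'
#' `tidy()` returns the per-pair results tibble; `glance()` returns the
#' one-row multiplicity ledger (pairs enumerated / filtered / untestable /
#' tested, Bonferroni m, FDR level, discoveries).
#'
#' @param x an `epi_scan` or `epi_pair_test` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy epi_scan
#' @export
tidy.epi_scan <- function(x, ...) x$results

#' @rdname tidy.epi_scan
#' @method glance epi_scan
#' @export
glance.epi_scan <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_pairs_enumerated = x$n_pairs_enumerated,
    n_pairs_filtered = x$n_pairs_filtered,
    n_pairs_untestable = x$n_pairs_untestable,
    n_pairs_tested = x$n_pairs_tested,
    bonferroni_m = x$bonferroni_m,
    fdr_q = x$fdr_q,
    n_significant_fdr = if (nrow(x$results) > 0)
      sum(x$results$significant_fdr) else 0L)
}

#' @rdname tidy.epi_scan
#' @method tidy epi_lm
#' @export
tidy.epi_lm <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(term = names(cf) %||% paste0("x", seq_along(cf)),
                 estimate = unname(cf))
}

#' @rdname tidy.epi_scan
#' @method glance epi_lm
#' @export
glance.epi_lm <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rss = x$rss, rank = x$rank,
                 n_used = x$n_used, df_residual = x$df_residual)
}

#' @rdname tidy.epi_scan
#' @method tidy epi_replication
#' @export
tidy.epi_replication <- function(x, ...) x$results

#' @rdname tidy.epi_scan
#' @method glance epi_replication
#' @export
glance.epi_replication <- function(x, ...) {
  tibble::tibble(
    bonferroni_m = x$bonferroni_m,
    best_p = if (x$bonferroni_m > 0) x$best$p else NA_real_,
    corrected_p = x$corrected_p,
    replicated = x$replicated,
    n_locus1_snps = length(x$locus1_snps),
    n_locus2_snps = length(x$locus2_snps))
}

#' @importFrom rlang %||%
NULL
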
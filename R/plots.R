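# ggplot2 diagnostics: QQ plots of interaction P values and the 9-cell
# genotype-combination boxplot for a single pair.

#' QQ plot of interaction P values
#'
#' Observed -log10 P against uniform order-statistic expectations, with the
#' identity line. Deviation above the diagonal in the tail indicates signal
#' (or confounding/inflation when global).
#'
#' @param p_list vector of P values.
#' @return A ggplot object.
#' @export
plot_qq <- function(p_list) {
  qq <- qq_points(p_list)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(P))),
                  y = expression(Observed ~ -log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @param object an `epi_scan` object.
#' @param ... unused.
#' @method autoplot epi_scan
#' @export
autoplot.epi_scan <- function(object, ...) {
  plot_qq(object$results$p) +
    ggplot2::ggtitle(sprintf("QQ plot, %d pairs tested",
                             object$n_pairs_tested))
}

#' Trait distribution across the nine genotype combinations of a SNP pair
#'
#' Boxplots of the trait for each combination of the two genotypes, the
#' standard picture of an interaction (a combination-specific shift that the
#' marginal rows/columns do not predict).
#'
#' @param y trait vector.
#' @param g1,g2 dosage vectors.
#' @param snp1_id,snp2_id axis labels.
#' @return A ggplot object.
#' @export
plot_interaction <- function(y, g1, g2, snp1_id = "SNP 1", snp2_id = "SNP 2") {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  d <- tibble::tibble(y = y[ok],
                      g1 = factor(g1[ok], levels = 0:2),
                      g2 = factor(g2[ok], levels = 0:2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g2, y = .data$y)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~g1, nrow = 1,
                        labeller = ggplot2::labeller(
                          g1 = function(v) paste0(snp1_id, " = ", v))) +
    ggplot2::labs(x = paste(snp2_id, "dosage"), y = "trait") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
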
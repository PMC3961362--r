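# Sliding-window linkage-disequilibrium pruning.

#' Squared genotype-dosage correlation between two SNPs
#'
#' Pearson correlation of dosage codes on the pairwise-complete subset,
#' squared. Invariant to effect-allele orientation (g vs 2 - g). When either
#' vector is constant on the complete-case subset, r-squared is undefined and
#' `NA` is returned; callers treat that as "do not prune on this pair".
#'
#' @param g1,g2 equal-length dosage vectors (0/1/2/NA).
#' @return Numeric in `[0, 1]`, or `NA` if undefined.
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]
  y <- g2[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

# r2 matrix for a set of columns, pairwise-complete; NA where undefined
.r2_matrix <- function(codes) {
  suppressWarnings(r <- stats::cor(codes, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- NA_real_
  r2
}

#' Window-based LD pruning
#'
#' Greedy within-window elimination with the conventional
#' `--indep-pairwise WINDOW STEP R2` semantics: within each window of
#' `window_snps` consecutive retained SNPs (per chromosome), while any
#' retained pair has r-squared above `r2_max`, one member of the
#' worst-offending pair is removed — the one with the lower call rate, ties
#' broken toward the later position. The window slides by `step_snps`, and
#' full sweeps repeat until a sweep removes nothing, so on completion no pair
#' of kept SNPs within any window placement exceeds `r2_max`.
#'
#' The surviving SNP set is not required to be identical to any particular
#' reference implementation; the guarantee is the post-condition above.
#'
#' @param genotypes an `epi_geno` object with SNPs sorted by
#'   (chromosome, position).
#' @param window_snps window size in SNPs.
#' @param step_snps slide in SNPs; must satisfy `window_snps > step_snps > 0`.
#' @param r2_max maximum tolerated pairwise r-squared among kept SNPs.
#' @return A list of class `epi_prune`: `kept_snp_ids` (ordered),
#'   `removed_snp_ids`, and `parameters`.
#' @export
ld_prune <- function(genotypes, window_snps = 50, step_snps = 5,
                     r2_max = 0.5) {
  stopifnot(window_snps > step_snps, step_snps > 0, r2_max >= 0)
  snps <- genotypes$snps
  ord <- order(match(snps$chr, unique(snps$chr)), snps$pos)
  if (!identical(ord, seq_len(nrow(snps)))) {
    stop("SNPs must be sorted by (chromosome, position) before pruning")
  }
  cr <- snp_call_rate(genotypes)
  kept <- rep(TRUE, nrow(snps))

  for (ch in unique(snps$chr)) {
    chr_idx <- which(snps$chr == ch)
    repeat {
      changed <- FALSE
      offset <- 1L
      repeat {
        cand <- chr_idx[kept[chr_idx]]
        if (offset > length(cand)) break
        win <- cand[offset:min(offset + window_snps - 1L, length(cand))]
        if (length(win) >= 2) {
          r2 <- .r2_matrix(genotypes$codes[, win, drop = FALSE])
          while (any(r2 > r2_max, na.rm = TRUE)) {
            worst <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
            a <- win[worst[1]]
            b <- win[worst[2]]
            drop_snp <- if (cr[a] < cr[b]) a
                        else if (cr[b] < cr[a]) b
                        else max(a, b)           # tie -> later position
            kept[drop_snp] <- FALSE
            changed <- TRUE
            w <- which(win == drop_snp)
            r2[w, ] <- NA_real_
            r2[, w] <- NA_real_
          }
        }
        if (offset + window_snps - 1L >= length(cand)) break
        offset <- offset + step_snps
      }
      if (!changed) break
    }
  }
  structure(
    list(kept_snp_ids = snps$snp_id[kept],
         removed_snp_ids = snps$snp_id[!kept],
         parameters = c(window_snps = window_snps, step_snps = step_snps,
                        r2_max = r2_max)),
    class = "epi_prune"
  )
}

#' @export
print.epi_prune <- function(x, ...) {
  p <- x$parameters
  cat("<epi_prune> indep-pairwise ", p[["window_snps"]], " ",
      p[["step_snps"]], " ", p[["r2_max"]], ": kept ",
      length(x$kept_snp_ids), ", removed ", length(x$removed_snp_ids),
      "\n", sep = "")
  invisible(x)
}

#' Write prune results as .prune.in / .prune.out ID lists
#'
#' @param prune an `epi_prune` object.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_prune <- function(prune, prefix) {
  writeLines(prune$kept_snp_ids, paste0(prefix, ".prune.in"))
  writeLines(prune$removed_snp_ids, paste0(prefix, ".prune.out"))
  invisible(prefix)
}
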
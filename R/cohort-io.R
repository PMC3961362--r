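# Phenotype/covariate tables and the results TSV.

# columns written by write_results(), in order
RESULT_COLUMNS <- c("snp1", "snp2", "chr1", "chr2", "pos1", "pos2", "n_used",
                    "F", "df1", "df2", "p", "p_bonferroni", "q_bh",
                    "r2_marginal", "r2_full", "delta_r2",
                    "delta_r2_vs_single", "min_cell_count")

.parse_pheno_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "na"))
  if (ncol(tab) < 3 || toupper(names(tab)[1]) != "FID" ||
      toupper(names(tab)[2]) != "IID") {
    stop(what, " file must be whitespace-delimited with FID IID leading columns")
  }
  ids <- as.character(tab[[2]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ID in ", what, " file: ",
         ids[anyDuplicated(ids)][1])
  }
  vals <- tab[, -(1:2), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      if (any(bad)) {
        stop("non-numeric value '", v[bad][1], "' in column ",
             names(vals)[j], " of ", what, " file")
      }
      v <- num
    }
    v[!is.na(v) & v == -9] <- NA_real_   # PLINK missing sentinel
    vals[[j]] <- v
  }
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), vals)
}

#' Read phenotype and covariate files into a cohort table
#'
#' Both files are whitespace-delimited with header line `FID IID <cols...>`.
#' Rows are joined on IID (full join): samples present in only one file keep
#' `NA` in the other file's columns and are dropped later by complete-case
#' logic. The sentinel `-9` and literal `NA` are mapped to missing.
#'
#' @param pheno_path phenotype file; its first non-ID column (or `trait`)
#'   becomes the trait.
#' @param covar_path covariate file (e.g. age, sex, bmi).
#' @param trait which phenotype column to treat as the trait; default the
#'   first non-ID column.
#' @return A tibble with columns `sample_id`, `trait`, then any further
#'   phenotype columns, then covariates.
#' @export
read_cohort_table <- function(pheno_path, covar_path = NULL, trait = NULL) {
  ph <- .parse_pheno_file(pheno_path, "phenotype")
  if (is.null(trait)) trait <- names(ph)[2]
  if (!trait %in% names(ph)) stop("trait column '", trait, "' not in phenotype file")
  names(ph)[names(ph) == trait] <- "trait"
  ph <- ph[, c("sample_id", "trait",
               setdiff(names(ph), c("sample_id", "trait"))), drop = FALSE]
  if (!is.null(covar_path)) {
    cv <- .parse_pheno_file(covar_path, "covariate")
    clash <- intersect(setdiff(names(cv), "sample_id"), names(ph))
    if (length(clash) > 0) {
      stop("column(s) present in both files: ", paste(clash, collapse = ", "))
    }
    ph <- merge(ph, cv, by = "sample_id", all = TRUE, sort = FALSE)
  }
  out <- tibble::as_tibble(ph)
  out[order(out$sample_id), , drop = FALSE]
}

.format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write scan results to a TSV file
#'
#' One row per tested pair, fixed column order, rows sorted by p ascending
#' with ties broken by SNP IDs so output is deterministic. Numeric fields are
#' printed with 17 significant digits so a round-trip read reproduces them
#' exactly. Optional provenance lines are written first, prefixed `# `.
#'
#' @param scan an `epi_scan` object (or a tibble of results).
#' @param path output file.
#' @param provenance optional named character vector written as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(scan, path, provenance = NULL) {
  res <- if (inherits(scan, "epi_scan")) scan$results else tibble::as_tibble(scan)
  if (nrow(res) > 0) {
    res <- res[order(res$p, res$snp1, res$snp2), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  }
  writeLines(paste(RESULT_COLUMNS, collapse = "\t"), con)
  if (nrow(res) > 0) {
    num_cols <- c("F", "p", "p_bonferroni", "q_bh", "r2_marginal", "r2_full",
                  "delta_r2", "delta_r2_vs_single")
    cells <- lapply(RESULT_COLUMNS, function(cn) {
      v <- res[[cn]]
      if (cn %in% num_cols) .format_num(v) else as.character(v)
    })
    writeLines(do.call(paste, c(cells, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path results file; `# `-prefixed provenance lines are skipped.
#' @return A tibble with the standard result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(snp1 = "character",
                                          snp2 = "character",
                                          chr1 = "character",
                                          chr2 = "character"))
  tibble::as_tibble(tab)
}
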
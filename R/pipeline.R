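# Pipeline configuration and subcommand dispatch. All randomness flows from
# the config seed; outputs carry a provenance header and contain no
# timestamps, so identical config + seed gives bit-identical files.

PIPELINE_DEFAULTS <- list(
  trait = "trait",
  covariates = "age,sex,bmi",
  mind = 0.90,            # minimum sample call rate
  geno = 0.90,            # minimum SNP call rate
  hwe = 0.001,
  min_cell = 10,
  fdr = 0.25,
  prune_window = 50, prune_step = 5, prune_r2 = 0.5,
  replication_window_kb = 100, replication_alpha = 0.05,
  near_anchor_kb = 1000,
  seed = 1,
  # simulate subcommand
  n_samples = 2091, n_snps = 304, maf_min = 0.1, maf_max = 0.5,
  ld_rho = 0, sigma = 6.5,
  interaction_snp1 = NA, interaction_snp2 = NA, interaction_varfrac = NA,
  sample_missing_rate = 0, snp_missing_rate = 0
)

#' Read a plain-text pipeline configuration
#'
#' One `key: value` pair per line; `#` starts a comment. Unknown keys are
#' kept verbatim (paths such as `bfile`, `pheno`, `covar`, `out`, `anchor`,
#' `results`, replication coordinates). Known numeric settings default to
#' the conventional values: call rates 0.90, HWE alpha 0.001, minimum cell
#' count 10, FDR 0.25, pruning 50/5/0.5.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (flags win over
#'   file values).
#' @return A named list of settings.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- PIPELINE_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) stop("malformed config line: ", ln)
      cfg[[m[2]]] <- m[3]
    }
  }
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  }
  # coerce numerics where the default is numeric
  for (nm in names(PIPELINE_DEFAULTS)) {
    if (is.numeric(PIPELINE_DEFAULTS[[nm]]) && !is.null(cfg[[nm]])) {
      cfg[[nm]] <- suppressWarnings(as.numeric(cfg[[nm]]))
    }
  }
  cfg
}

.cfg_covariates <- function(config) {
  cv <- trimws(strsplit(as.character(config$covariates), ",")[[1]])
  cv[nzchar(cv)]
}

.cfg_require <- function(config, keys, subcommand) {
  miss <- keys[!vapply(keys, function(k)
    !is.null(config[[k]]) && !identical(config[[k]], NA), logical(1))]
  if (length(miss) > 0) {
    stop("subcommand '", subcommand, "' requires config key(s): ",
         paste(miss, collapse = ", "))
  }
}

.provenance <- function(config, subcommand, counts = NULL) {
  keep <- vapply(config, function(v) length(v) == 1 && !is.na(v), logical(1))
  cfg <- config[keep]
  cfg <- cfg[order(names(cfg))]
  c(tool = paste0("epihub ", as.character(utils::packageVersion("epihub"))),
    subcommand = subcommand,
    config = paste0(names(cfg), "=", unlist(cfg), collapse = " "),
    counts)
}

.load_cohort_inputs <- function(config, subcommand) {
  .cfg_require(config, c("bfile", "pheno", "covar"), subcommand)
  g <- read_plink_bed(paste0(config$bfile, ".bed"))
  cohort <- read_cohort_table(config$pheno, config$covar,
                              trait = if (identical(config$trait, "trait"))
                                NULL else config$trait)
  list(genotypes = g, cohort = cohort)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic cohort), `qc` (call-rate and
#' Hardy-Weinberg filters; writes a QC report and kept-ID lists), `prune`
#' (LD pruning; writes `.prune.in`/`.prune.out`), `pairs` (all-pairs scan),
#' `hub` (single-anchor scan), `replicate` (locus-window replication) and
#' `qq` (QQ export from an existing results file). Results and QQ tables go
#' to files under the `out` prefix; progress counts go to `message()`
#' (stderr). Outputs carry a `# `-provenance header and no timestamps.
#'
#' @param config a config list from [read_pipeline_config()] (or a config
#'   file path).
#' @param subcommand one of the stage names above.
#' @return Invisibly, a list with the produced artifact paths and the main
#'   in-memory result object.
#' @export
run_pipeline <- function(config, subcommand = c("simulate", "qc", "prune",
                                                "pairs", "hub", "replicate",
                                                "qq")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_pipeline_config(config)
  .cfg_require(config, "out", subcommand)
  out <- config$out

  if (subcommand == "simulate") {
    interactions <- NULL
    if (!is.na(config$interaction_snp1)) {
      interactions <- tibble::tibble(
        snp1 = as.integer(config$interaction_snp1),
        snp2 = as.integer(config$interaction_snp2),
        v_aa = as.numeric(config$interaction_varfrac))
    }
    set.seed(config$seed)
    maf <- stats::runif(config$n_snps, config$maf_min, config$maf_max)
    spec <- simulation_spec(
      n_samples = config$n_samples, maf = maf, n_snps = config$n_snps,
      ld_rho = config$ld_rho, sigma = config$sigma,
      interactions = interactions,
      sample_missing_rate = config$sample_missing_rate,
      snp_missing_rate = config$snp_missing_rate,
      seed = config$seed)
    stem <- simulate_cohort_files(spec, dirname(out), basename(out))
    message("simulate: wrote ", stem, ".{bed,bim,fam,pheno,covar}")
    return(invisible(list(prefix = stem, spec = spec)))
  }

  if (subcommand == "qc") {
    inp <- .load_cohort_inputs(config, "qc")
    qc <- apply_qc(inp$genotypes, sample_cr_min = config$mind,
                   snp_cr_min = config$geno, hwe_alpha = config$hwe)
    report_path <- paste0(out, ".qc_report.tsv")
    write_qc_report(qc$report, report_path)
    writeLines(qc$genotypes$samples, paste0(out, ".qc.samples"))
    writeLines(qc$genotypes$snps$snp_id, paste0(out, ".qc.snps"))
    message("qc: removed ", nrow(qc$report$samples_removed), " samples, ",
            nrow(qc$report$snps_removed), " SNPs")
    return(invisible(list(report = report_path, qc = qc)))
  }

  if (subcommand == "prune") {
    .cfg_require(config, "bfile", "prune")
    g <- read_plink_bed(paste0(config$bfile, ".bed"))
    pr <- ld_prune(g, window_snps = config$prune_window,
                   step_snps = config$prune_step, r2_max = config$prune_r2)
    write_prune(pr, out)
    message("prune: kept ", length(pr$kept_snp_ids), " of ",
            nrow(g$snps), " SNPs")
    return(invisible(list(prune = pr,
                          prune_in = paste0(out, ".prune.in"))))
  }

  if (subcommand == "qq") {
    .cfg_require(config, "results", "qq")
    res <- read_results(config$results)
    qq <- qq_points(res$p)
    path <- paste0(out, ".qq.tsv")
    utils::write.table(format(as.data.frame(qq), digits = 17, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(qq = path)))
  }

  if (subcommand %in% c("pairs", "hub")) {
    inp <- .load_cohort_inputs(config, subcommand)
    covars <- .cfg_covariates(config)
    scan <- if (subcommand == "pairs") {
      all_pairs_scan(inp$genotypes, inp$cohort, trait = "trait",
                     covariates = covars, min_cell = config$min_cell,
                     fdr_q = config$fdr)
    } else {
      .cfg_require(config, "anchor", "hub")
      hub_scan(inp$genotypes, inp$cohort, anchor = config$anchor,
               trait = "trait", covariates = covars,
               min_cell = config$min_cell, fdr_q = config$fdr,
               near_anchor_kb = config$near_anchor_kb)
    }
    counts <- c(n_pairs_enumerated = scan$n_pairs_enumerated,
                n_pairs_filtered = scan$n_pairs_filtered,
                n_pairs_untestable = scan$n_pairs_untestable,
                n_pairs_tested = scan$n_pairs_tested)
    res_path <- paste0(out, ".results.tsv")
    write_results(scan, res_path,
                  provenance = .provenance(config, subcommand, counts))
    qq_path <- paste0(out, ".qq.tsv")
    if (nrow(scan$results) > 0) write_qq(scan, qq_path)
    message(subcommand, ": ", scan$n_pairs_enumerated, " enumerated -> ",
            scan$n_pairs_tested, " tested -> ",
            if (nrow(scan$results) > 0) sum(scan$results$significant_fdr)
            else 0L,
            " significant at FDR ", config$fdr)
    return(invisible(list(results = res_path, qq = qq_path, scan = scan)))
  }

  # replicate
  inp <- .load_cohort_inputs(config, "replicate")
  .cfg_require(config, c("rep_snp1", "rep_chr1", "rep_pos1",
                         "rep_snp2", "rep_chr2", "rep_pos2"), "replicate")
  spec <- replication_spec(
    snp1_id = config$rep_snp1, snp2_id = config$rep_snp2,
    chr1 = config$rep_chr1, pos1 = as.integer(config$rep_pos1),
    chr2 = config$rep_chr2, pos2 = as.integer(config$rep_pos2),
    window_kb = config$replication_window_kb,
    alpha = config$replication_alpha,
    covariates = .cfg_covariates(config))
  rep <- locus_replicate(spec, inp$genotypes, inp$cohort,
                         min_cell = config$min_cell)
  res_path <- paste0(out, ".replication.tsv")
  write_results(rep$results, res_path,
                provenance = .provenance(
                  config, "replicate",
                  c(bonferroni_m = rep$bonferroni_m,
                    corrected_p = format(rep$corrected_p, digits = 17),
                    replicated = rep$replicated)))
  message("replicate: m = ", rep$bonferroni_m, ", corrected p = ",
          signif(rep$corrected_p, 3), ", replicated = ", rep$replicated)
  invisible(list(results = res_path, replication = rep))
}

# Minimal subcommand-style argument parser used by the inst/cli wrapper.
# args: c(subcommand, "--key", "value", ...). "--indep-pairwise W S R2"
# consumes three values; dashes in flag names map to underscores.
.parse_cli_args <- function(args) {
  if (length(args) < 1) stop("usage: epihub <subcommand> [--flag value ...]")
  subcommand <- args[[1]]
  args <- args[-1]
  overrides <- list()
  config_path <- NULL
  i <- 1
  while (i <= length(args)) {
    flag <- args[[i]]
    if (!startsWith(flag, "--")) stop("expected a --flag, got: ", flag)
    key <- gsub("-", "_", substring(flag, 3))
    if (key == "indep_pairwise") {
      if (i + 3 > length(args)) stop("--indep-pairwise needs WINDOW STEP R2")
      overrides$prune_window <- args[[i + 1]]
      overrides$prune_step <- args[[i + 2]]
      overrides$prune_r2 <- args[[i + 3]]
      i <- i + 4
      next
    }
    if (i + 1 > length(args)) stop("flag ", flag, " needs a value")
    val <- args[[i + 1]]
    if (key == "config") config_path <- val else overrides[[key]] <- val
    i <- i + 2
  }
  list(subcommand = subcommand, config_path = config_path,
       overrides = overrides)
}
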
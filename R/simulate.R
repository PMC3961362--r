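# Seeded cohort simulator: HWE genotypes with optional AR(1)-latent LD,
# age/sex/BMI covariates, and a quantitative trait with planted additive,
# dominance and pairwise interaction effects.

#' Specify a simulated cohort
#'
#' Effects can be given directly as coefficients (`a`, `d`, `i_aa`, ...) or
#' as target fractions of total trait variance (`v_a`, `v_d`, `v_aa`, ...).
#' Variance fractions are converted to coefficients analytically from the
#' moments of the genotype coding under Hardy-Weinberg equilibrium and SNP
#' independence; interaction fractions use the variance of the interaction
#' column residualized against the marginal additive/dominance space (the
#' centered cross-product), so a planted "pure" interaction fraction v is
#' what the scan's delta R-squared estimates.
#'
#' @param n_samples number of individuals.
#' @param maf minor-allele frequency per SNP, each in `(0, 0.5]`; recycled
#'   `n_snps` long if `n_snps` is given.
#' @param n_snps optional; defaults to `length(maf)`.
#' @param chr chromosome label per SNP (default all "1").
#' @param pos base-pair position per SNP (default 5 kb spacing).
#' @param ld_rho AR(1) correlation of the latent haplotype Gaussian in
#'   `[0, 1)`; 0 gives independent SNPs.
#' @param age_range uniform range of age in years.
#' @param bmi_mean,bmi_sd normal parameters of BMI in kg/m^2.
#' @param intercept trait intercept (mg/dl for the HDL-like default).
#' @param covariate_betas named vector with elements `age`, `sex`, `bmi`.
#' @param snp_effects data frame of per-SNP effects: column `snp` (index or
#'   ID) plus coefficients `a`, `d` and/or variance fractions `v_a`, `v_d`.
#' @param interactions data frame of pair effects: columns `snp1`, `snp2`
#'   plus coefficients `i_aa`, `i_ad`, `i_da`, `i_dd` and/or fractions
#'   `v_aa`, `v_ad`, `v_da`, `v_dd`.
#' @param sigma residual standard deviation (> 0).
#' @param sample_missing_rate,snp_missing_rate missingness rates; scalars or
#'   vectors (per sample / per SNP). Missing calls are the union of the two
#'   Bernoulli masks.
#' @param seed mandatory integer seed; stage streams (genotypes, covariates,
#'   phenotype, missingness) are derived from it with fixed offsets so each
#'   stage is reproducible in isolation.
#' @return A validated list of class `epi_sim_spec`.
#' @export
simulation_spec <- function(n_samples, maf, n_snps = length(maf),
                            chr = NULL, pos = NULL, ld_rho = 0,
                            age_range = c(45, 64),
                            bmi_mean = 28, bmi_sd = 4.5,
                            intercept = 50,
                            covariate_betas = c(age = -0.05, sex = 8,
                                                bmi = -0.4),
                            snp_effects = NULL, interactions = NULL,
                            sigma = 6.5,
                            sample_missing_rate = 0, snp_missing_rate = 0,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf > 0.5)) stop("MAFs must lie in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(chr)) chr <- rep("1", n_snps)
  chr <- rep_len(as.character(chr), n_snps)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(n_snps), chr, FUN = seq_along) * 5000L
  }
  spec <- structure(
    list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
         maf = maf, chr = chr, pos = as.integer(pos), ld_rho = ld_rho,
         age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         intercept = intercept, covariate_betas = covariate_betas,
         snp_effects = if (!is.null(snp_effects))
           tibble::as_tibble(snp_effects),
         interactions = if (!is.null(interactions))
           tibble::as_tibble(interactions),
         sigma = sigma,
         sample_missing_rate = sample_missing_rate,
         snp_missing_rate = snp_missing_rate,
         seed = as.integer(seed)),
    class = "epi_sim_spec"
  )
  .resolve_effects(spec)   # validates variance fractions sum < 1
  spec
}

# analytic moments of the default 0/1/2 + heterozygote coding under HWE
.var_x <- function(p) 2 * p * (1 - p)
.var_z <- function(p) { h <- 2 * p * (1 - p); h * (1 - h) }

# Convert the effect spec to concrete coefficients. Returns list with
# tibbles `snp` (idx, a, d) and `pair` (idx1, idx2, i_aa, i_ad, i_da, i_dd),
# plus v_base (covariate variance), v_total (implied total trait variance).
.resolve_effects <- function(spec) {
  cb <- spec$covariate_betas
  v_base <- cb[["age"]]^2 * diff(spec$age_range)^2 / 12 +
    cb[["sex"]]^2 * 0.25 + cb[["bmi"]]^2 * spec$bmi_sd^2

  snp_idx <- function(s) {
    if (is.numeric(s)) as.integer(s) else match(as.character(s), spec$snp_ids)
  }
  snp <- spec$snp_effects
  pair <- spec$interactions
  getcol <- function(df, nm) if (!is.null(df) && nm %in% names(df))
    ifelse(is.na(df[[nm]]), 0, df[[nm]]) else rep(0, NROW(df))

  # variance contributed by coefficient-specified effects, and the summed
  # target fractions of fraction-specified effects
  v_coef <- 0
  v_frac <- 0
  if (!is.null(snp)) {
    ia <- snp_idx(snp$snp)
    p <- spec$maf[ia]
    v_coef <- v_coef + sum(getcol(snp, "a")^2 * .var_x(p)) +
      sum(getcol(snp, "d")^2 * .var_z(p))
    v_frac <- v_frac + sum(getcol(snp, "v_a")) + sum(getcol(snp, "v_d"))
  }
  if (!is.null(pair)) {
    i1 <- snp_idx(pair$snp1); i2 <- snp_idx(pair$snp2)
    p1 <- spec$maf[i1]; p2 <- spec$maf[i2]
    v_coef <- v_coef +
      sum(getcol(pair, "i_aa")^2 * .var_x(p1) * .var_x(p2)) +
      sum(getcol(pair, "i_ad")^2 * .var_x(p1) * .var_z(p2)) +
      sum(getcol(pair, "i_da")^2 * .var_z(p1) * .var_x(p2)) +
      sum(getcol(pair, "i_dd")^2 * .var_z(p1) * .var_z(p2))
    v_frac <- v_frac + sum(getcol(pair, "v_aa")) + sum(getcol(pair, "v_ad")) +
      sum(getcol(pair, "v_da")) + sum(getcol(pair, "v_dd"))
  }
  if (v_frac >= 1) stop("variance fractions must sum to less than 1")
  v_total <- (v_base + v_coef + spec$sigma^2) / (1 - v_frac)

  coef_from <- function(v, term_var) {
    ifelse(v > 0, sqrt(v * v_total / term_var), 0)
  }
  snp_out <- NULL
  if (!is.null(snp)) {
    ia <- snp_idx(snp$snp)
    p <- spec$maf[ia]
    snp_out <- tibble::tibble(
      idx = ia,
      a = getcol(snp, "a") + coef_from(getcol(snp, "v_a"), .var_x(p)),
      d = getcol(snp, "d") + coef_from(getcol(snp, "v_d"), .var_z(p)))
  }
  pair_out <- NULL
  if (!is.null(pair)) {
    i1 <- snp_idx(pair$snp1); i2 <- snp_idx(pair$snp2)
    p1 <- spec$maf[i1]; p2 <- spec$maf[i2]
    pair_out <- tibble::tibble(
      idx1 = i1, idx2 = i2,
      i_aa = getcol(pair, "i_aa") +
        coef_from(getcol(pair, "v_aa"), .var_x(p1) * .var_x(p2)),
      i_ad = getcol(pair, "i_ad") +
        coef_from(getcol(pair, "v_ad"), .var_x(p1) * .var_z(p2)),
      i_da = getcol(pair, "i_da") +
        coef_from(getcol(pair, "v_da"), .var_z(p1) * .var_x(p2)),
      i_dd = getcol(pair, "i_dd") +
        coef_from(getcol(pair, "v_dd"), .var_z(p1) * .var_z(p2)))
  }
  list(snp = snp_out, pair = pair_out, v_base = v_base, v_total = v_total)
}

# spec$snp_ids helper (referenced when effects name SNPs by ID)
#' @export
`$.epi_sim_spec` <- function(x, name) {
  if (name == "snp_ids") {
    sprintf("snp%04d", seq_len(.subset2(x, "n_snps")))
  } else {
    .subset2(x, name)
  }
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual carries two latent haplotype Gaussians per chromosome with
#' AR(1) correlation `ld_rho` along the SNP index; an allele is the minor
#' allele when its latent value falls below the MAF quantile. Genotype =
#' allele sum, so marginal genotype frequencies are the HWE proportions at
#' the specified MAF and adjacent-SNP dosage correlation is tuned by
#' `ld_rho`. With `ld_rho = 0` the draw reduces to independent binomials.
#'
#' @param spec an [simulation_spec()].
#' @return An [geno_matrix()] object (no missingness; see
#'   [simulate_cohort()]).
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed + 1L)
  n <- spec$n_samples
  m <- spec$n_snps
  codes <- matrix(0L, n, m)
  if (spec$ld_rho == 0) {
    codes <- matrix(stats::rbinom(n * m, 2L, rep(spec$maf, each = n)), n, m)
  } else {
    rho <- spec$ld_rho
    sq <- sqrt(1 - rho^2)
    thr <- stats::qnorm(spec$maf)
    for (ch in unique(spec$chr)) {
      cols <- which(spec$chr == ch)
      h1 <- matrix(0, n, length(cols))
      h2 <- matrix(0, n, length(cols))
      for (k in seq_along(cols)) {
        e1 <- stats::rnorm(n)
        e2 <- stats::rnorm(n)
        if (k == 1) {
          h1[, k] <- e1; h2[, k] <- e2
        } else {
          h1[, k] <- rho * h1[, k - 1] + sq * e1
          h2[, k] <- rho * h2[, k - 1] + sq * e2
        }
        codes[, cols[k]] <- (h1[, k] < thr[cols[k]]) + (h2[, k] < thr[cols[k]])
      }
    }
  }
  snps <- tibble::tibble(snp_id = spec$snp_ids, chr = spec$chr,
                         pos = spec$pos, allele1 = "A", allele2 = "G")
  geno_matrix(codes, snps = snps,
              samples = sprintf("I%05d", seq_len(n)))
}

#' Simulate cohort covariates
#'
#' Age uniform over `age_range`, sex Bernoulli(0.5) coded 0/1, BMI normal.
#'
#' @param spec an [simulation_spec()].
#' @return A tibble with `sample_id`, `age`, `sex`, `bmi`.
#' @export
simulate_covariates <- function(spec) {
  set.seed(spec$seed + 2L)
  n <- spec$n_samples
  tibble::tibble(
    sample_id = sprintf("I%05d", seq_len(n)),
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, spec$bmi_mean, spec$bmi_sd))
}

#' Simulate the quantitative trait
#'
#' `Y = intercept + Z beta + sum(a_i x_i + d_i z_i) + sum(pair terms) + e`,
#' `e ~ N(0, sigma^2)`, using the same default additive/dominance coding as
#' the test. Variance-fraction effect specs are converted to coefficients
#' analytically (see [simulation_spec()]).
#'
#' @param genotypes an `epi_geno` (pre-missingness codes).
#' @param covariates covariate tibble from [simulate_covariates()].
#' @param spec an [simulation_spec()].
#' @return Numeric trait vector; the resolved coefficients are attached as
#'   attribute `"effects"`.
#' @export
simulate_phenotype <- function(genotypes, covariates, spec) {
  set.seed(spec$seed + 3L)
  eff <- .resolve_effects(spec)
  cb <- spec$covariate_betas
  n <- spec$n_samples
  y <- spec$intercept + cb[["age"]] * covariates$age +
    cb[["sex"]] * covariates$sex + cb[["bmi"]] * covariates$bmi
  if (!is.null(eff$snp)) {
    for (r in seq_len(nrow(eff$snp))) {
      e <- encode_genotype(genotypes$codes[, eff$snp$idx[r]])
      y <- y + eff$snp$a[r] * e$x + eff$snp$d[r] * e$z
    }
  }
  if (!is.null(eff$pair)) {
    for (r in seq_len(nrow(eff$pair))) {
      e1 <- encode_genotype(genotypes$codes[, eff$pair$idx1[r]])
      e2 <- encode_genotype(genotypes$codes[, eff$pair$idx2[r]])
      y <- y + eff$pair$i_aa[r] * e1$x * e2$x +
        eff$pair$i_ad[r] * e1$x * e2$z +
        eff$pair$i_da[r] * e1$z * e2$x +
        eff$pair$i_dd[r] * e1$z * e2$z
    }
  }
  y <- y + stats::rnorm(n, 0, spec$sigma)
  attr(y, "effects") <- eff
  y
}

#' Simulate a complete cohort in memory
#'
#' Draws genotypes, covariates and trait, then injects missing genotype
#' calls as the union of per-sample and per-SNP Bernoulli masks. The trait is
#' generated from the pre-masking genotypes: missingness emulates assay
#' failure, not biology.
#'
#' @param spec an [simulation_spec()].
#' @return A list with `genotypes` (an `epi_geno`, missingness injected) and
#'   `cohort` (tibble `sample_id`, `trait`, `age`, `sex`, `bmi`).
#' @export
simulate_cohort <- function(spec) {
  g <- simulate_genotypes(spec)
  cv <- simulate_covariates(spec)
  y <- simulate_phenotype(g, cv, spec)
  set.seed(spec$seed + 4L)
  n <- spec$n_samples; m <- spec$n_snps
  sr <- rep_len(spec$sample_missing_rate, n)
  cr <- rep_len(spec$snp_missing_rate, m)
  if (any(sr > 0) || any(cr > 0)) {
    mask <- matrix(stats::runif(n * m) < sr, n, m) |
      matrix(stats::runif(n * m) < rep(cr, each = n), n, m)
    codes <- g$codes
    codes[mask] <- NA_integer_
    g <- geno_matrix(codes, snps = g$snps, samples = g$samples)
  }
  cohort <- tibble::tibble(sample_id = cv$sample_id,
                           trait = as.numeric(y),
                           age = cv$age, sex = cv$sex, bmi = cv$bmi)
  list(genotypes = g, cohort = cohort,
       effects = attr(y, "effects"))
}

#' Simulate a cohort and write it as PLINK + phenotype/covariate files
#'
#' Writes `<prefix>.bed/.bim/.fam`, `<prefix>.pheno` (FID IID trait) and
#' `<prefix>.covar` (FID IID age sex bmi). Re-reading through
#' [read_plink_bed()] and [read_cohort_table()] reproduces the in-memory
#' cohort exactly.
#'
#' @param spec an [simulation_spec()].
#' @param out_dir writable directory.
#' @param prefix file name prefix inside `out_dir`.
#' @return The full path prefix, invisibly.
#' @export
simulate_cohort_files <- function(spec, out_dir, prefix = "sim") {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  sim <- simulate_cohort(spec)
  stem <- file.path(out_dir, prefix)
  write_plink_bed(sim$genotypes, stem)
  ph <- data.frame(FID = sim$cohort$sample_id, IID = sim$cohort$sample_id,
                   trait = sprintf("%.17g", sim$cohort$trait))
  utils::write.table(ph, paste0(stem, ".pheno"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  cv <- data.frame(FID = sim$cohort$sample_id, IID = sim$cohort$sample_id,
                   age = sprintf("%.17g", sim$cohort$age),
                   sex = sim$cohort$sex,
                   bmi = sprintf("%.17g", sim$cohort$bmi))
  utils::write.table(cv, paste0(stem, ".covar"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(stem)
}
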
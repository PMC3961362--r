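# The cohort simulator: genotype frequencies, LD, effect calibration,
# missingness, file round trips.

test_that("genotype frequencies match HWE closed form at the given MAF", {
  spec <- simulation_spec(n_samples = 50000, maf = 0.3, n_snps = 1, seed = 701)
  g <- simulate_genotypes(spec)
  freq <- tabulate(g$codes[, 1] + 1L, 3L) / 50000
  expected <- c(0.49, 0.42, 0.09)  # (1-p)^2, 2p(1-p), p^2 at p = 0.3
  se <- sqrt(expected * (1 - expected) / 50000)
  expect_true(all(abs(freq - expected) < 3 * se))
})

test_that("empirical MAF recovers the spec for all SNPs", {
  spec <- simulation_spec(n_samples = 20000, maf = c(0.05, 0.1, 0.25, 0.5),
                          seed = 702)
  g <- simulate_genotypes(spec)
  maf_hat <- colMeans(g$codes) / 2
  se <- sqrt(spec$maf * (1 - spec$maf) / (2 * 20000))
  expect_true(all(abs(maf_hat - spec$maf) < 3 * se))
})

test_that("the same seed reproduces the cohort exactly", {
  spec <- simulation_spec(n_samples = 300, maf = runif(10, 0.1, 0.5),
                          n_snps = 10, ld_rho = 0.4,
                          sample_missing_rate = 0.02, seed = 703)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$cohort, b$cohort)
})

test_that("AR(1) latent LD raises adjacent r2 and pruning then removes SNPs", {
  spec0 <- simulation_spec(n_samples = 3000, maf = rep(0.3, 20),
                           ld_rho = 0, seed = 704)
  spec9 <- simulation_spec(n_samples = 3000, maf = rep(0.3, 20),
                           ld_rho = 0.9, seed = 704)
  g0 <- simulate_genotypes(spec0)
  g9 <- simulate_genotypes(spec9)
  adj_r2 <- function(g) mean(vapply(1:19, function(j)
    genotype_r2(g$codes[, j], g$codes[, j + 1]), numeric(1)))
  expect_lt(adj_r2(g0), 0.05)
  expect_gt(adj_r2(g9), adj_r2(g0) + 0.3)
  pr <- ld_prune(g9, window_snps = 10, step_snps = 2, r2_max = 0.5)
  expect_gt(length(pr$removed_snp_ids), 0)
})

test_that("simulated SNPs fail the HWE filter at about the nominal rate", {
  spec <- simulation_spec(n_samples = 800, maf = runif(3000, 0.1, 0.5),
                          n_snps = 3000, seed = 705)
  g <- simulate_genotypes(spec)
  p <- apply(g$codes, 2, function(col) {
    tab <- tabulate(col + 1L, 3L)
    hwe_exact_test(tab[3], tab[2], tab[1])
  })
  expect_lt(mean(p < 0.001), 0.001 + 3 * sqrt(0.001 * 0.999 / 3000))
})

test_that("with no genetic effects, trait variance is covariate + residual", {
  spec <- simulation_spec(n_samples = 30000, maf = c(0.3, 0.4), seed = 706)
  sim <- simulate_cohort(spec)
  eff <- epihub:::.resolve_effects(spec)
  expected_var <- eff$v_base + spec$sigma^2
  expect_equal(var(sim$cohort$trait), expected_var, tolerance = 0.05)
})

test_that("planted additive variance fraction is recovered by single_snp_r2", {
  incs <- vapply(1:10, function(s) {
    spec <- simulation_spec(n_samples = 20000, maf = c(0.3, 0.4),
                            snp_effects = data.frame(snp = 1, v_a = 0.05),
                            seed = 710 + s)
    sim <- simulate_cohort(spec)
    as.numeric(single_snp_r2(sim$cohort$trait,
                             sim$cohort[, c("age", "sex", "bmi")],
                             sim$genotypes$codes[, 1]))
  }, numeric(1))
  mc_se <- sd(incs) / sqrt(length(incs))
  expect_lt(abs(mean(incs) - 0.05), 3 * mc_se + 0.002)
})

test_that("planted pure interaction fraction is recovered by delta_r2", {
  deltas <- vapply(1:20, function(s) {
    spec <- simulation_spec(n_samples = 10000, maf = c(0.3, 0.4),
                            interactions = data.frame(snp1 = 1, snp2 = 2,
                                                      v_aa = 0.01),
                            seed = 730 + s)
    sim <- simulate_cohort(spec)
    interaction_f_test(sim$cohort$trait,
                       sim$cohort[, c("age", "sex", "bmi")],
                       sim$genotypes$codes[, 1],
                       sim$genotypes$codes[, 2])$delta_r2
  }, numeric(1))
  expect_gt(mean(deltas), 0.008)
  expect_lt(mean(deltas), 0.012)
})

test_that("cohort files round trip through the readers", {
  d <- tempdir()
  spec <- simulation_spec(n_samples = 120, maf = runif(8, 0.2, 0.5),
                          n_snps = 8, snp_missing_rate = 0.03, seed = 707)
  stem <- simulate_cohort_files(spec, d, prefix = "rtsim")
  sim <- simulate_cohort(spec)
  g <- read_plink_bed(paste0(stem, ".bed"))
  cohort <- read_cohort_table(paste0(stem, ".pheno"), paste0(stem, ".covar"))
  expect_identical(unname(g$codes), unname(sim$genotypes$codes))
  ord <- match(sim$cohort$sample_id, cohort$sample_id)
  expect_equal(cohort$trait[ord], sim$cohort$trait)
  expect_equal(cohort$bmi[ord], sim$cohort$bmi)
})

test_that("a planted high-missingness sample is removed at the 0.90 threshold", {
  spec <- simulation_spec(n_samples = 150, maf = runif(40, 0.2, 0.5),
                          n_snps = 40,
                          sample_missing_rate = c(0.5, rep(0, 149)),
                          seed = 708)
  sim <- simulate_cohort(spec)
  qc <- apply_qc(sim$genotypes)
  expect_identical(qc$report$samples_removed$sample_id, "I00001")
})

test_that("spec validation rejects impossible parameters", {
  expect_error(simulation_spec(100, maf = 0.6, seed = 1), "MAF")
  expect_error(simulation_spec(100, maf = 0.3, seed = 1, sigma = 0), "sigma")
  expect_error(simulation_spec(100, maf = 0.3, ld_rho = 1, seed = 1), "ld_rho")
  expect_error(simulation_spec(100, maf = 0.3), "seed")
  expect_error(
    simulation_spec(100, maf = c(0.3, 0.4),
                    interactions = data.frame(snp1 = 1, snp2 = 2, v_aa = 1.2),
                    seed = 1),
    "less than 1")
})
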
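# Genotype coding, least squares, and the 4-df interaction F-test.

test_that("genotype codings follow their definitions and propagate NA", {
  e <- encode_genotype(c(0, 1, 2, NA))
  expect_equal(e$x, c(0, 1, 2, NA))
  expect_equal(e$z, c(0, 1, 0, NA))
  ec <- encode_genotype(c(0, 1, 2, NA), coding = "cordell")
  expect_equal(ec$x, c(-1, 0, 1, NA))
  expect_equal(ec$z, c(-0.5, 0.5, -0.5, NA))
  expect_error(encode_genotype(c(0, 3)), "dosage")
})

test_that("fit_linear matches a normal-equations oracle and handles rank", {
  set.seed(401)
  n <- 100
  X <- cbind(1, matrix(rnorm(n * 4), n))
  y <- X %*% c(2, 1, -1, 0.5, 0) + rnorm(n)
  f <- fit_linear(y, X)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f$coefficients), drop(beta), tolerance = 1e-8)
  expect_equal(f$rss, sum((y - X %*% beta)^2), tolerance = 1e-8)
  expect_equal(f$rank, 5)

  # duplicated column: same fit, rank unchanged by the duplicate
  fdup <- fit_linear(y, cbind(X, X[, 2]))
  expect_equal(fdup$rank, 5)
  expect_equal(fdup$rss, f$rss, tolerance = 1e-10)
  expect_equal(fdup$r_squared, f$r_squared, tolerance = 1e-12)

  # exact linear response
  y2 <- X %*% c(1, 2, 3, 4, 5)
  f2 <- fit_linear(y2, X)
  expect_lt(f2$rss, 1e-18 * sum(y2^2))
  expect_equal(f2$r_squared, 1, tolerance = 1e-10)

  expect_error(fit_linear(rep(3, n), X), "zero variance")
  expect_s3_class(glance(f), "tbl_df")
})

test_that("interaction F-test equals the nested lm/anova oracle, with and without missingness", {
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 250
    Z <- cbind(age = runif(n, 45, 64), sex = rbinom(n, 1, .5),
               bmi = rnorm(n, 28, 4))
    g1 <- rbinom(n, 2, 0.35)
    g2 <- rbinom(n, 2, 0.45)
    y <- 40 + 0.1 * Z[, 1] + 2 * Z[, 2] + 0.2 * g1 +
      0.3 * g1 * g2 * (s %% 2) + rnorm(n, 0, 3)
    if (s > 10) {      # exercise complete-case handling
      g1[sample(n, 12)] <- NA
      y[sample(n, 5)] <- NA
    }
    cc <- complete.cases(y, g1, g2, Z)
    ft <- interaction_f_test(y, Z, g1, g2)
    orac <- oracle_pair_f(y[cc], Z[cc, ], g1[cc], g2[cc])
    expect_equal(ft$n_used, sum(cc))
    expect_equal(ft$F, orac$F, tolerance = 1e-10)
    expect_equal(ft$p, orac$p, tolerance = 1e-10)
    expect_equal(ft$r2_marginal, orac$r2_marginal, tolerance = 1e-10)
    expect_equal(ft$r2_full, orac$r2_full, tolerance = 1e-10)
    expect_gte(ft$delta_r2, 0)
    expect_equal(sum(ft$cell_counts), sum(cc))
  }
})

test_that("F, p and R2 are invariant to the genotype coding", {
  for (s in 1:10) {
    set.seed(420 + s)
    n <- 200
    Z <- cbind(age = runif(n, 45, 64))
    g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
    y <- 10 + 0.05 * Z[, 1] + 0.1 * g1 * g2 + rnorm(n)
    a <- interaction_f_test(y, Z, g1, g2, coding = "additive_dominance")
    b <- interaction_f_test(y, Z, g1, g2, coding = "cordell")
    expect_equal(a$F, b$F, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
    expect_equal(a$r2_marginal, b$r2_marginal, tolerance = 1e-10)
    expect_equal(a$r2_full, b$r2_full, tolerance = 1e-10)
  }
})

test_that("F computed from RSS equals F computed from the R2 identity", {
  set.seed(431)
  n <- 300
  Z <- cbind(age = runif(n, 45, 64), bmi = rnorm(n, 28, 4))
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
  y <- 5 + 0.1 * g1 + 0.2 * g1 * g2 + rnorm(n)
  ft <- interaction_f_test(y, Z, g1, g2)
  f_from_r2 <- ((ft$r2_full - ft$r2_marginal) / ft$df_num) /
    ((1 - ft$r2_full) / ft$df_den)
  expect_equal(ft$F, f_from_r2, tolerance = 1e-10)
})

test_that("degenerate pairs are flagged untestable, never p = 1", {
  set.seed(441)
  n <- 120
  y <- rnorm(n)
  g1 <- rbinom(n, 2, 0.3)
  ft <- interaction_f_test(y, NULL, g1, rep(0, n))
  expect_false(ft$testable)
  expect_identical(ft$reason, "monomorphic")
  expect_true(is.na(ft$p))

  # monomorphic only on the complete-case subset
  g2 <- rbinom(n, 2, 0.4)
  g2[g1 != 1] <- NA            # variation confined to dropped samples
  g1m <- g1; g1m[g1 != 1] <- 1L
  ftc <- interaction_f_test(y, NULL, g1m, g2)
  expect_false(ftc$testable)

  # disjoint-carrier binary SNPs: interaction column identically zero -> q = 0
  gA <- rep(0, n); gA[1:30] <- 1
  gB <- rep(0, n); gB[31:60] <- 1
  ftq <- interaction_f_test(y, NULL, gA, gB)
  expect_false(ftq$testable)
  expect_identical(ftq$reason, "collinear_interaction")
})

test_that("numerator df adapts to the realized interaction rank", {
  set.seed(451)
  n <- 400
  # g2 has only two genotype classes -> z2 aliased with x2, q = 2 not 4
  g1 <- rbinom(n, 2, 0.4)
  g2 <- rbinom(n, 1, 0.3)
  y <- rnorm(n) + 0.2 * g1 * g2
  ft <- interaction_f_test(y, NULL, g1, g2)
  expect_true(ft$testable)
  expect_equal(ft$df_num, 2)
  # fully populated cells give the full 4 df
  g3 <- rbinom(n, 2, 0.45)
  ft4 <- interaction_f_test(y, NULL, g1, g3)
  expect_equal(ft4$df_num, 4)
})

test_that("single_snp_r2 matches the nested-R2 oracle and recovers planted effects", {
  set.seed(461)
  n <- 500
  Z <- cbind(age = runif(n, 45, 64))
  g <- rbinom(n, 2, 0.3)
  y <- 2 + 0.1 * Z[, 1] + 0.8 * g + rnorm(n, 0, 2)
  inc <- single_snp_r2(y, Z, g)
  m0 <- lm(y ~ Z)
  m1 <- lm(y ~ Z + g + I(g == 1))
  expect_equal(as.numeric(inc),
               summary(m1)$r.squared - summary(m0)$r.squared,
               tolerance = 1e-10)
  expect_false(attr(inc, "monomorphic"))

  # independent SNP: increment near zero
  set.seed(462)
  inc0 <- single_snp_r2(rnorm(5000), NULL, rbinom(5000, 2, 0.3))
  expect_lt(as.numeric(inc0), 0.005)

  incm <- single_snp_r2(y, Z, rep(2, n))
  expect_equal(as.numeric(incm), 0)
  expect_true(attr(incm, "monomorphic"))
})

test_that("planted 1% pure interaction is detected with sensible delta R2", {
  spec <- simulation_spec(n_samples = 2000, maf = c(0.3, 0.4), n_snps = 2,
                          interactions = data.frame(snp1 = 1, snp2 = 2,
                                                    v_aa = 0.01),
                          seed = 1)
  sim <- simulate_cohort(spec)
  ft <- interaction_f_test(sim$cohort$trait,
                           sim$cohort[, c("age", "sex", "bmi")],
                           sim$genotypes$codes[, 1], sim$genotypes$codes[, 2])
  expect_lt(ft$p, 0.01)
  expect_gt(ft$delta_r2, 0.002)
  expect_lt(ft$delta_r2, 0.025)
})
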
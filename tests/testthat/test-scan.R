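# Pair filtering, scans, multiplicity correction and QQ export.

test_that("minimum cell-count filter has an inclusive boundary and fails zero cells", {
  make_pair <- function(min_target) {
    # 9 balanced cells, then thin one cell to the target count
    g1 <- rep(0:2, each = 30)
    g2 <- rep(rep(0:2, times = 3), each = 10)
    keep <- rep(TRUE, 90)
    drop_from <- which(g1 == 2 & g2 == 2)
    keep[drop_from[seq_len(10 - min_target)]] <- FALSE
    list(g1 = g1[keep], g2 = g2[keep])
  }
  p10 <- make_pair(10)
  expect_true(min_cell_filter(p10$g1, p10$g2)$pass)       # exactly 10 passes
  p9 <- make_pair(9)
  f9 <- min_cell_filter(p9$g1, p9$g2)
  expect_false(f9$pass)                                    # 9 fails
  expect_equal(min(f9$cell_counts), 9)
  p0 <- make_pair(0)
  expect_false(min_cell_filter(p0$g1, p0$g2)$pass)         # empty cell fails
})

test_that("all-pairs scan bookkeeping matches a direct recount", {
  g <- make_geno(500, maf = runif(10, 0.15, 0.5), seed = 501)
  cohort <- make_cohort(g, seed = 501)
  scan <- all_pairs_scan(g, cohort)
  expect_equal(scan$n_pairs_enumerated, choose(10, 2))

  # independent recount of filter-passing pairs
  recount <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    cells <- table(factor(g$codes[, i], 0:2), factor(g$codes[, j], 0:2))
    if (min(cells) >= 10) recount <- recount + 1
  }
  expect_equal(scan$n_pairs_tested, recount)
  expect_equal(scan$bonferroni_m, recount)
  expect_equal(nrow(scan$results), recount)
  expect_equal(scan$n_pairs_enumerated,
               scan$n_pairs_tested + scan$n_pairs_filtered +
                 scan$n_pairs_untestable)
  # per-row corrections are consistent with the ledger
  expect_equal(scan$results$p_bonferroni,
               pmin(1, scan$results$p * recount))
  expect_equal(scan$results$q_bh, p.adjust(scan$results$p, "BH"),
               tolerance = 1e-15)
})

test_that("a planted interacting pair ranks first among null SNPs", {
  maf <- runif(30, 0.25, 0.5); maf[1] <- 0.3; maf[2] <- 0.4
  spec <- simulation_spec(n_samples = 2000, maf = maf, n_snps = 30,
                          interactions = data.frame(snp1 = 1, snp2 = 2,
                                                    v_aa = 0.02),
                          seed = 502)
  sim <- simulate_cohort(spec)
  scan <- all_pairs_scan(sim$genotypes, sim$cohort)
  expect_identical(c(scan$results$snp1[1], scan$results$snp2[1]),
                   c("snp0001", "snp0002"))
  expect_true(scan$results$significant_fdr[1])
})

test_that("two SNPs failing the cell filter give an empty result set", {
  set.seed(503)
  g1 <- c(rep(0L, 95), rep(1L, 4), 2L)    # rare cells < 10 guaranteed
  g2 <- rbinom(100, 2, 0.5)
  g <- geno_matrix(cbind(g1, g2), snps = tibble::tibble(
    snp_id = c("a", "b"), chr = "1", pos = c(100L, 200L),
    allele1 = "A", allele2 = "G"))
  cohort <- make_cohort(g, seed = 503)
  scan <- all_pairs_scan(g, cohort)
  expect_equal(scan$n_pairs_enumerated, 1)
  expect_equal(scan$n_pairs_tested, 0)
  expect_equal(nrow(scan$results), 0)
})

test_that("bonferroni_adjust follows min(1, p*m)", {
  expect_equal(bonferroni_adjust(0.001, 50), 0.05)
  expect_equal(bonferroni_adjust(0.1, 100), 1.0)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(0.1, 0), "m must")
})

test_that("BH step-up matches the definition oracle", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  res <- bh_fdr(p, q = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(res$reject, oracle_bh_reject(p, 0.05))

  expect_identical(bh_fdr(rep(1, 5), 0.25)$reject, rep(FALSE, 5))
  expect_identical(bh_fdr(0.01, 0.05)$reject, TRUE)
  expect_length(bh_fdr(numeric(0))$reject, 0)

  set.seed(504)
  for (i in 1:20) {
    p <- runif(50)^2
    q <- runif(1, 0.01, 0.4)
    expect_identical(bh_fdr(p, q)$reject, oracle_bh_reject(p, q))
  }
})

test_that("qq_points pairs sorted observations with uniform quantiles", {
  qq <- qq_points(c(0.4, 0.2, 0.8, 0.6))
  expect_equal(qq$expected, -log10(c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(qq$observed, -log10(c(0.2, 0.4, 0.6, 0.8)))
  qq1 <- qq_points(0.03)
  expect_equal(qq1$expected, -log10(0.5))
  expect_warning(qq_points(c(0, 0.5)), "clamped")
  # null p-values hug the diagonal within KS bounds
  set.seed(505)
  qqn <- qq_points(runif(2000))
  dev <- max(abs(10^(-qqn$observed) - 10^(-qqn$expected)))
  expect_lt(dev, 1.63 / sqrt(2000))  # KS 1% critical value
})

test_that("scan results are invariant to sample and SNP ordering", {
  g <- make_geno(600, maf = runif(8, 0.25, 0.5), seed = 506)
  cohort <- make_cohort(g, seed = 506)
  base <- all_pairs_scan(g, cohort)
  set.seed(507)
  sp <- sample(600); cp <- sample(8)
  g2 <- geno_matrix(g$codes[sp, cp], snps = g$snps[cp, ],
                    samples = g$samples[sp])
  perm <- all_pairs_scan(g2, cohort[sample(600), ])
  key <- function(r) paste(pmin(r$snp1, r$snp2), pmax(r$snp1, r$snp2))
  expect_setequal(key(base$results), key(perm$results))
  ord <- match(key(base$results), key(perm$results))
  expect_equal(base$results$F, perm$results$F[ord], tolerance = 1e-12)
  expect_equal(base$results$p, perm$results$p[ord], tolerance = 1e-12)
})

test_that("fast scan path agrees with the one-pair episcore path", {
  g <- make_geno(400, maf = runif(12, 0.2, 0.5), seed = 508)
  codes <- g$codes
  codes[sample(length(codes), 150)] <- NA_integer_  # force slow path on some
  g <- geno_matrix(codes, snps = g$snps, samples = g$samples)
  cohort <- make_cohort(g, seed = 508)
  scan <- all_pairs_scan(g, cohort, min_cell = 5)
  Z <- as.matrix(cohort[, c("age", "sex", "bmi")])
  for (k in seq_len(nrow(scan$results))) {
    r <- scan$results[k, ]
    ft <- interaction_f_test(cohort$trait, Z,
                             g$codes[, r$snp1], g$codes[, r$snp2])
    expect_equal(r$F, ft$F, tolerance = 1e-8)
    expect_equal(r$p, ft$p, tolerance = 1e-8)
    expect_equal(r$delta_r2, ft$delta_r2, tolerance = 1e-8)
    expect_equal(r$delta_r2_vs_single, ft$delta_r2_vs_single,
                 tolerance = 1e-8)
    expect_equal(r$n_used, ft$n_used)
  }
})

test_that("hub scan: planted partner found, nulls quiet, proximity flagged", {
  maf <- runif(201, 0.25, 0.5); maf[1] <- 0.3; maf[2] <- 0.4
  spec <- simulation_spec(n_samples = 3000, maf = maf, n_snps = 201,
                          interactions = data.frame(snp1 = 1, snp2 = 2,
                                                    v_aa = 0.015),
                          seed = 509)
  sim <- simulate_cohort(spec)
  hub <- hub_scan(sim$genotypes, sim$cohort, anchor = "snp0001")
  expect_equal(hub$n_pairs_enumerated, 200)
  expect_identical(hub$results$snp2[1], "snp0002")
  expect_true(hub$results$significant_fdr[1])
  # partner 5 kb from the anchor on the same chromosome is flagged
  expect_true(all(hub$results$near_anchor[
    abs(hub$results$pos2 - sim$genotypes$snps$pos[1]) <= 1e6]))

  expect_error(hub_scan(sim$genotypes, sim$cohort, anchor = "nope"),
               "not in panel")
  gm <- sim$genotypes
  codes <- gm$codes; codes[, 3] <- 0L
  gm <- geno_matrix(codes, snps = gm$snps, samples = gm$samples)
  expect_error(hub_scan(gm, sim$cohort, anchor = "snp0003"), "monomorphic")
})

test_that("null hub scans rarely produce FDR discoveries", {
  # under the global null, BH rejects something in about a q fraction of
  # replicates; "discovery-free in most replicates" is the calibrated claim
  with_disc <- vapply(1:12, function(s) {
    spec <- simulation_spec(n_samples = 600, maf = runif(101, 0.25, 0.5),
                            n_snps = 101, seed = 5100 + s)
    sim <- simulate_cohort(spec)
    hub <- hub_scan(sim$genotypes, sim$cohort, anchor = "snp0001")
    sum(hub$results$significant_fdr) > 0
  }, logical(1))
  expect_lte(sum(with_disc), 6)
})
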
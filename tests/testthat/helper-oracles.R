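# Independent oracles and fixture builders shared across tests. Each oracle
# is written from the definition, independently of the package's code path.

# Exact HWE het-count pmf by direct log-factorial evaluation:
# P(h | n, m) = n! / (hom_r! h! hom_c!) * 2^h * m! (2n-m)! / (2n)!
oracle_hwe_pmf <- function(n, m) {
  het <- seq.int(m %% 2L, min(m, 2L * n - m), by = 2L)
  hom_r <- (m - het) / 2
  hom_c <- n - het - hom_r
  lp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(het) -
    lfactorial(hom_c) + het * log(2) +
    lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  list(het = het, pmf = exp(lp))
}

oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  m <- min(2 * n_hom1 + n_het, 2 * n_hom2 + n_het)
  d <- oracle_hwe_pmf(n, m)
  p_obs <- d$pmf[d$het == n_het]
  min(1, sum(d$pmf[d$pmf <= p_obs * (1 + 1e-12)]))
}

# Nested-model F-test for a pair via lm()/anova(), the generic least-squares
# route the package does not use internally.
oracle_pair_f <- function(y, Z, g1, g2) {
  x1 <- g1; z1 <- as.numeric(g1 == 1)
  x2 <- g2; z2 <- as.numeric(g2 == 1)
  dat <- data.frame(y = y, as.data.frame(Z), x1 = x1, z1 = z1,
                    x2 = x2, z2 = z2)
  covs <- colnames(Z)
  f0 <- stats::reformulate(c(covs, "x1", "z1", "x2", "z2"), response = "y")
  f1 <- stats::reformulate(c(covs, "x1", "z1", "x2", "z2",
                             "I(x1*x2)", "I(x1*z2)", "I(z1*x2)", "I(z1*z2)"),
                           response = "y")
  m0 <- stats::lm(f0, data = dat)
  m1 <- stats::lm(f1, data = dat)
  a <- stats::anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       r2_marginal = summary(m0)$r.squared,
       r2_full = summary(m1)$r.squared)
}

# Benjamini-Hochberg step-up straight from the definition.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# Bit-level BED decoder written independently of the package reader.
oracle_bed_decode <- function(path, n, m) {
  raw <- readBin(path, "raw", n = file.size(path))[-(1:3)]
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8)
  pairs <- bits[seq(1, 8, 2), , drop = FALSE] +
    2L * bits[seq(2, 8, 2), , drop = FALSE]
  vals <- as.vector(pairs)
  bytes_per_snp <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    v <- vals[((j - 1) * 4 * bytes_per_snp + 1):(j * 4 * bytes_per_snp)][1:n]
    out[, j] <- c(2L, NA, 1L, 0L)[v + 1L]
  }
  out
}

# Random genotype matrix fixture with optional missingness.
make_geno <- function(n, maf, miss = 0, chr = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(maf)
  codes <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  if (miss > 0) codes[runif(n * m) < miss] <- NA_integer_
  if (is.null(chr)) chr <- rep("1", m)
  pos <- as.integer(stats::ave(seq_len(m), chr, FUN = seq_along) * 1000L)
  geno_matrix(codes,
              snps = tibble::tibble(snp_id = sprintf("rs%03d", seq_len(m)),
                                    chr = chr, pos = pos,
                                    allele1 = "A", allele2 = "G"))
}

# Small cohort fixture around a genotype object.
make_cohort <- function(g, y = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(g$samples)
  age <- runif(n, 45, 64); sex <- rbinom(n, 1, .5); bmi <- rnorm(n, 28, 4)
  if (is.null(y)) y <- 40 - 0.05 * age + 5 * sex - 0.3 * bmi + rnorm(n, 0, 6)
  tibble::tibble(sample_id = g$samples, trait = y,
                 age = age, sex = sex, bmi = bmi)
}
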
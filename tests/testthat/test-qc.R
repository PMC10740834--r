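test_that("missingness filter matches a brute-force per-column count", {
  g <- random_geno(100, 50, seed = 7, missing_rate = 0.08)
  res <- filter_missingness(g, qc_thresholds(max_missing_rate = 0.05))
  keep_oracle <- sapply(seq_len(50), function(j) {
    sum(is.na(g$dosages[, j])) / 100 <= 0.05
  })
  expect_identical(colnames(res$genotypes$dosages),
                   colnames(g$dosages)[keep_oracle])
  expect_equal(res$report$removed + res$report$remaining, 50)

  # no missing data: identity
  g0 <- random_geno(50, 20, seed = 1)
  expect_identical(filter_missingness(g0)$genotypes$dosages, g0$dosages)
})

test_that("MAF filter removes monomorphic variants and keeps the boundary", {
  d <- cbind(rep(0, 100),                      # monomorphic
             rbinom(100, 2, 0.3),
             c(rep(1, 10), rep(0, 90)))        # freq exactly 0.05
  g <- manual_geno(d)
  res <- filter_maf(g, qc_thresholds(min_maf = 0.05))
  expect_false("1_1000" %in% colnames(res$genotypes$dosages))
  expect_true("1_3000" %in% colnames(res$genotypes$dosages))  # p = 0.05 kept

  g2 <- random_geno(200, 40, seed = 3, maf = c(0.01, 0.3))
  res2 <- filter_maf(g2)
  keep_oracle <- pmin(g2$freqs, 1 - g2$freqs) >= 0.05
  expect_identical(colnames(res2$genotypes$dosages),
                   colnames(g2$dosages)[keep_oracle])
})

test_that("HWE chi-square matches hand arithmetic", {
  expect_equal(hwe_test(25, 50, 25), 1)  # perfect HWE, chi-square 0
  # (0,100,0): chi-square = 25 + 50 + 25 = 100
  expect_equal(hwe_test(0, 100, 0), pchisq(100, 1, lower.tail = FALSE))
  expect_equal(hwe_test(0, 0, 50), 1)    # monomorphic passes
})

test_that("HWE test holds its type-I error under the null", {
  set.seed(42)
  n <- 400
  reject <- replicate(10000, {
    p <- runif(1, 0.1, 0.5)
    geno <- rbinom(n, 2, p)
    hwe_test(sum(geno == 2), sum(geno == 1), sum(geno == 0)) < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.01)
})

test_that("LD pruning removes duplicates within the window only", {
  x <- rbinom(80, 2, 0.4)
  # duplicate 1 kb apart -> later copy pruned
  g <- manual_geno(cbind(x, x), bp = c(1000L, 2000L))
  res <- ld_prune(g, qc_thresholds(ld_window_bp = 50000))
  expect_equal(n_variants(res$genotypes), 1)
  expect_equal(res$genotypes$map$bp, 1000L)  # earlier variant kept
  # identical columns 100 kb apart with a 50 kb window -> both retained
  g2 <- manual_geno(cbind(x, x), bp = c(1000L, 101000L))
  expect_equal(n_variants(ld_prune(g2)$genotypes), 2)
})

test_that("greedy LD pruning matches an exhaustive pairwise oracle", {
  cfg <- tiny_config(n_individuals = 150, n_variants = 400, n_chromosomes = 1,
                     chromosome_length_bp = 4e5, ld_rho = 0.85, seed = 17)
  g <- simulate_genotypes(cfg)
  thr <- qc_thresholds(ld_r2_max = 0.5, ld_window_bp = 5000)
  res <- ld_prune(g, thr)

  # independent oracle: full r^2 matrix first, then the same greedy rule
  d <- impute_mean(g)
  r2 <- cor(d)^2
  keep <- rep(TRUE, ncol(d))
  for (i in seq_len(ncol(d))) {
    if (!keep[i]) next
    for (j in seq_len(ncol(d))) {
      if (j <= i || !keep[j]) next
      if (g$map$bp[j] - g$map$bp[i] <= 5000 && r2[i, j] > 0.5) keep[j] <- FALSE
    }
  }
  expect_gt(sum(!keep), 0)  # the fixture must actually exercise pruning
  expect_identical(colnames(res$genotypes$dosages), colnames(d)[keep])

  # invariant: no surviving ordered pair within the window exceeds the cap
  ds <- res$genotypes
  dd <- impute_mean(ds)
  for (i in seq_len(ncol(dd) - 1)) {
    j <- i + 1
    while (j <= ncol(dd) && ds$map$bp[j] - ds$map$bp[i] <= 5000) {
      expect_lte(cor(dd[, i], dd[, j])^2, 0.5 + 1e-12)
      j <- j + 1
    }
  }
})

test_that("the QC chain applies filters in order and accounts for every variant", {
  g <- random_geno(120, 100, seed = 5, maf = c(0.02, 0.5), missing_rate = 0.03)
  res <- run_qc(g, qc_thresholds(max_missing_rate = 0.04))
  expect_identical(res$report$stage, c("missingness", "maf", "hwe", "ld_prune"))
  expect_equal(sum(res$report$removed) + n_variants(res$genotypes), 100)
  expect_equal(res$report$remaining[4], n_variants(res$genotypes))
})

test_that("mean imputation preserves per-variant frequencies", {
  g <- random_geno(100, 30, seed = 9, missing_rate = 0.1)
  d <- impute_mean(g)
  expect_false(anyNA(d))
  expect_equal(unname(colMeans(d) / 2), unname(g$freqs), tolerance = 1e-12)
})
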
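test_that("realized allele frequencies match the binomial sampling oracle", {
  cfg <- tiny_config(n_individuals = 5000, n_variants = 40,
                     maf_range = c(0.3, 0.3), ld_rho = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_true(all(abs(g$freqs - 0.3) <= 3 * se))
})

test_that("adjacent-variant LD tracks ld_rho and vanishes at rho = 0", {
  n <- 600
  cfg0 <- tiny_config(n_individuals = n, n_variants = 200, n_chromosomes = 1,
                      ld_rho = 0, seed = 8)
  g0 <- simulate_genotypes(cfg0)
  r2 <- sapply(seq_len(199), function(j) {
    cor(g0$dosages[, j], g0$dosages[, j + 1])^2
  })
  # under independence E[r^2] ~ 1/n
  expect_lt(mean(r2), 3 / n)

  cfg5 <- tiny_config(n_individuals = n, n_variants = 200, n_chromosomes = 1,
                      ld_rho = 0.6, maf_range = c(0.2, 0.4), seed = 8)
  g5 <- simulate_genotypes(cfg5)
  r <- sapply(seq_len(199), function(j) {
    cor(g5$dosages[, j], g5$dosages[, j + 1])
  })
  expect_equal(mean(r), 0.6, tolerance = 0.05)
})

test_that("missing_rate = 0 leaves no missing dosages and seeds reproduce bits", {
  cfg <- tiny_config(seed = 21)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_false(anyNA(g1$dosages))
  expect_identical(g1$dosages, g2$dosages)
  g3 <- simulate_genotypes(tiny_config(seed = 22))
  expect_false(identical(g1$dosages, g3$dosages))

  gm <- simulate_genotypes(tiny_config(missing_rate = 0.1, seed = 21))
  expect_lt(abs(mean(is.na(gm$dosages)) - 0.1), 0.01)
})

test_that("map is position-sorted with unique positions and invalid configs error", {
  cfg <- tiny_config()
  g <- simulate_genotypes(cfg)
  expect_false(is.unsorted(order(g$map$chr, g$map$bp)))
  expect_false(anyDuplicated(g$map[c("chr", "bp")]) > 0)
  expect_error(sim_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(heritability = 0.5, n_qtl = 0), "n_qtl")
})

test_that("trait truth is consistent: tbv = centered QTL dosages x effects", {
  cfg <- tiny_config(seed = 13)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  Zq <- sweep(g$dosages[, tr$truth$qtl_indices], 2,
              2 * g$freqs[tr$truth$qtl_indices])
  expect_equal(drop(Zq %*% tr$truth$qtl_effects),
               tr$truth$true_breeding_values, tolerance = 1e-12)
  expect_equal(tr$truth$realized_h2, 0.5, tolerance = 1e-10)
})

test_that("zero heritability gives a pure fixed + noise phenotype", {
  cfg <- tiny_config(heritability = 0, seed = 4)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  expect_equal(var(tr$truth$true_breeding_values), 0)
  expect_equal(tr$truth$realized_h2, 0)
})

test_that("with zero fixed-effect variance, the trait is mean + genetics + noise", {
  cfg <- tiny_config(n_individuals = 500, fixed_effect_sd = 0, seed = 6)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  # no factor carries signal: correcting only removes OLS noise absorption
  yc <- correct_phenotypes(tr$pheno)
  centered <- tr$pheno$trait - mean(tr$pheno$trait)
  expect_gt(cor(yc$residual, centered), 0.95)
  # and correcting for no factors at all is exactly mean-centering
  yc0 <- correct_phenotypes(tr$pheno, factors = character(0))
  expect_equal(yc0$residual, centered, tolerance = 1e-10)
})

test_that("per-variant regression matches lm()", {
  g <- random_geno(60, 5, seed = 2)
  set.seed(9)
  y <- rnorm(60)
  reg <- gwas_regression(g$dosages, y)
  for (j in 1:5) {
    fit <- summary(lm(y ~ g$dosages[, j]))$coefficients
    expect_equal(reg$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(reg$se[j], fit[2, 2], tolerance = 1e-10)
  }
})

test_that("meta-analysis identities: single study, equal weights, pooled SE", {
  # single study: pooled effect is the study's effect
  m1 <- meta_fixed_effect(matrix(c(0.3, -0.2), 1), matrix(c(0.1, 0.05), 1), 50)
  expect_equal(m1$beta, c(0.3, -0.2))
  expect_equal(m1$se, c(0.1, 0.05))
  # equal SEs: pooled effect is the plain average
  m2 <- meta_fixed_effect(matrix(c(0.2, 0.6), 2, 1), matrix(0.1, 2, 1),
                          c(40, 40))
  expect_equal(m2$beta, 0.4)
  # inverse-variance pooling never increases the SE
  B <- matrix(rnorm(6), 3, 2)
  S <- matrix(runif(6, 0.05, 0.2), 3, 2)
  m3 <- meta_fixed_effect(B, S, c(10, 10, 10))
  expect_true(all(m3$se <= apply(S, 2, min) + 1e-12))
  expect_equal(m3$z, m3$beta / m3$se)
  expect_equal(m3$p, 2 * pnorm(-abs(m3$z)))
})

test_that("variants monomorphic in all cohorts are flagged with p = 1", {
  m <- meta_fixed_effect(matrix(c(NA, 0.5), 1), matrix(c(NA, 0.2), 1), 30)
  expect_true(m$flagged[1])
  expect_false(m$flagged[2])
  expect_equal(m$p[1], 1)
  expect_equal(m$beta[1], 0)
})

test_that("simulated meta statistics enrich true QTLs and are reproducible", {
  cfg <- tiny_config(seed = 31)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  ss1 <- simulate_meta_gwas(cfg, tr$truth)
  ss2 <- simulate_meta_gwas(cfg, tr$truth)
  expect_identical(ss1, ss2)
  # QTLs should be strongly enriched at the top of the p-value ranking:
  # effect sizes are heterogeneous, so ask for the larger QTLs to surface
  top1pct <- rank_variants(ss1$p, g$map, "pvalue_ascending")[1:3]
  expect_gte(length(intersect(top1pct, tr$truth$qtl_indices)), 2)
  expect_lt(median(ss1$p[tr$truth$qtl_indices]), 0.05)
  expect_gt(median(ss1$p[-tr$truth$qtl_indices]), 0.2)
})
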
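test_that("profile REML matches a 401-point grid search on the variance ratio", {
  cfg <- tiny_config(n_individuals = 150, n_variants = 400, seed = 71)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  y <- correct_phenotypes(tr$pheno)
  yv <- y$residual[match(rownames(g$dosages), y$id)]
  K <- build_grm(g)
  vc <- reml_one_kernel(yv, K)

  # independent profile likelihood evaluated on a fixed grid of gamma
  eg <- eigen(unclass(K), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, yv))
  xt <- drop(crossprod(eg$vectors, rep(1, length(yv))))
  n <- length(yv)
  prof <- function(gam) {
    w <- gam * lam + 1
    xtwx <- sum(xt^2 / w)
    mu <- sum(yt * xt / w) / xtwx
    q <- sum((yt - xt * mu)^2 / w)
    se2 <- q / (n - 1)
    -0.5 * ((n - 1) * log(se2) + sum(log(w)) + log(xtwx) + (n - 1))
  }
  grid <- 10^seq(-4, 4, length.out = 401)
  ll <- vapply(grid, prof, numeric(1))
  best <- grid[which.max(ll)]
  step <- 8 / 400  # grid spacing in log10 units
  expect_lte(abs(log10(vc$gamma) - log10(best)), step)
  expect_gte(vc$loglik, max(ll) - 1e-6)
})

test_that("REML heritability is near zero for pure noise", {
  hits <- 0
  for (s in 1:10) {
    g <- random_geno(500, 500, seed = 100 + s)
    set.seed(200 + s)
    y <- rnorm(500)
    vc <- reml_one_kernel(y, build_grm(g))
    h2 <- vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2)
    if (h2 < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("eigendecomposition REML agrees with direct covariance inversion", {
  cfg <- tiny_config(n_individuals = 100, n_variants = 300, seed = 81)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  yv <- correct_phenotypes(tr$pheno)$residual
  K <- unclass(build_grm(g))
  vc <- reml_one_kernel(yv, K)
  # recompute the restricted loglik at the optimum by direct inversion
  n <- length(yv)
  V <- vc$sigma_g2 * K + diag(vc$sigma_e2, n)
  Vi <- solve(V)
  X <- rep(1, n)
  XtViX <- drop(crossprod(X, Vi %*% X))
  mu <- drop(crossprod(X, Vi %*% yv)) / XtViX
  r <- yv - mu
  ll_direct <- -0.5 * (determinant(V)$modulus[1] + log(XtViX) +
                         drop(crossprod(r, Vi %*% r)))
  expect_equal(vc$loglik, ll_direct, tolerance = 1e-6)
  expect_equal(vc$mu, mu, tolerance = 1e-8)
})

test_that("aliased two-kernel fit recovers the single-kernel total variance", {
  cfg <- tiny_config(n_individuals = 150, n_variants = 300, seed = 91)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  yv <- correct_phenotypes(tr$pheno)$residual
  K <- build_grm(g)
  vc1 <- reml_one_kernel(yv, K)
  vc2 <- reml_two_kernels(yv, K, K)
  total2 <- sum(vc2$sigma_g2)
  expect_equal(total2, vc1$sigma_g2,
               tolerance = 1e-4 * max(vc1$sigma_g2, vc1$sigma_e2))
  expect_equal(vc2$sigma_e2, vc1$sigma_e2, tolerance = 1e-3)
})

test_that("two-kernel REML attains at least the better nested single-kernel loglik", {
  cfg <- tiny_config(n_individuals = 150, n_variants = 400, n_qtl = 8, seed = 95)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  yv <- correct_phenotypes(tr$pheno)$residual
  G <- build_grm(g)
  Gf <- ensure_psd(build_grm(g, subset = tr$truth$qtl_indices, label = "Gf"))
  ll1 <- max(reml_one_kernel(yv, G)$loglik, reml_one_kernel(yv, Gf)$loglik)
  vc2 <- reml_two_kernels(yv, Gf, G)
  expect_gte(vc2$loglik, ll1 - 1e-6)
  expect_true(vc2$converged)
})

test_that("a component simulated at zero is estimated near zero", {
  hits <- 0
  for (s in 1:10) {
    cfg <- tiny_config(n_individuals = 400, n_variants = 400,
                       seed = 300 + s)
    g <- simulate_genotypes(cfg)
    tr <- simulate_trait(g, cfg)  # trait built from the genome-wide kernel
    yv <- correct_phenotypes(tr$pheno)$residual
    G <- build_grm(g)
    # K1 is an unrelated random kernel: its variance share should fit ~0
    gnull <- random_geno(400, 400, seed = 900 + s)
    rownames(gnull$dosages) <- rownames(g$dosages)
    K1 <- ensure_psd(build_grm(gnull))
    vc <- reml_two_kernels(yv, K1, G)
    share <- vc$sigma_g2[1] / (sum(vc$sigma_g2) + vc$sigma_e2)
    if (share < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
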
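test_that("two-individual GRM matches hand arithmetic", {
  d <- matrix(c(0, 2), 2, 1)
  storage.mode(d) <- "double"
  g <- manual_geno(d)
  G <- build_grm(g)
  # p = 0.5, centered dosages (-1, 1), denominator 2 * 0.5 * 0.5 = 0.5
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
})

test_that("an explicit all-variant subset changes nothing and the diagonal is ~1", {
  g <- random_geno(50, 300, seed = 19, maf = c(0.1, 0.5))
  G1 <- build_grm(g)
  G2 <- build_grm(g, subset = seq_len(300))
  expect_equal(unclass(G1), unclass(G2))
  # VanRaden normalization: mean diagonal near 1 for unrelated individuals
  expect_equal(mean(diag(G1)), 1, tolerance = 0.1)
  expect_lt(max(abs(unclass(G1) - t(unclass(G1)))), 1e-12)
})

test_that("weight vectors rescale to mean one and preserve ordering", {
  w <- build_weight_vector(c(2, 0, 0, 0), selected = 1:4, panel_size = 4)
  expect_equal(as.numeric(w), c(4, 0, 0, 0))  # already mean 1 after squaring
  set.seed(2)
  eff <- rnorm(50)
  w2 <- build_weight_vector(eff, selected = 1:20, panel_size = 50)
  expect_equal(mean(w2), 1, tolerance = 1e-12)
  expect_equal(order(w2[1:20]), order(eff[1:20]^2))
  # unselected variants share a common baseline weight
  expect_equal(length(unique(round(w2[21:50], 12))), 1)
  expect_warning(wz <- build_weight_vector(c(0, 0), 1:2, 2), "uniform")
  expect_equal(as.numeric(wz), c(1, 1))
})

test_that("identity weights reduce the weighted GRM to the plain GRM", {
  g <- random_geno(40, 80, seed = 21)
  w <- build_weight_vector(rep(1, 80), selected = 1:80, panel_size = 80)
  expect_equal(unclass(build_weighted_grm(g, w)), unclass(build_grm(g)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a single positive weight gives a rank-1 kernel", {
  g <- random_geno(30, 4, seed = 5)
  w <- build_weight_vector(c(3, 0, 0, 0), selected = 1:4, panel_size = 4)
  K <- build_weighted_grm(g, w)
  d <- impute_mean(g)
  p <- colMeans(d) / 2
  z1 <- d[, 1] - 2 * p[1]
  expected <- as.numeric(w)[1] * tcrossprod(z1) / (2 * sum(p * (1 - p)))
  expect_equal(unclass(K), expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(abs(eigen(unclass(K))$values) > 1e-8), 1)
})

test_that("weighted GRM equals explicit per-variant summation", {
  g <- random_geno(40, 60, seed = 33)
  set.seed(34)
  w <- build_weight_vector(rnorm(60), selected = 1:60, panel_size = 60)
  K <- build_weighted_grm(g, w)
  d <- impute_mean(g)
  p <- colMeans(d) / 2
  cdenom <- 2 * sum(p * (1 - p))
  acc <- matrix(0, 40, 40)
  for (i in 1:60) {
    zi <- d[, i] - 2 * p[i]
    acc <- acc + as.numeric(w)[i] * tcrossprod(zi)
  }
  expect_lt(max(abs(unclass(K) - acc / cdenom)), 1e-10)
})

test_that("kernel blending is elementwise and exact at the endpoints", {
  g <- random_geno(25, 40, seed = 41)
  G <- build_grm(g)
  w <- build_weight_vector(rnorm(10), 1:10, 10)
  Sf <- build_weighted_grm(g, w, subset = 1:10, label = "Sf")
  expect_equal(unclass(blend_kernels(Sf, G, 0)), unclass(G),
               ignore_attr = TRUE)
  expect_equal(unclass(blend_kernels(Sf, G, 1)), unclass(Sf),
               ignore_attr = TRUE)
  mid <- blend_kernels(Sf, G, 0.5)
  expect_equal(unclass(mid), (unclass(Sf) + unclass(G)) / 2,
               ignore_attr = TRUE)
  expect_identical(attr(mid, "label"), "T")
})

test_that("kernels are invariant to individual reordering (up to permutation)", {
  g <- random_geno(30, 100, seed = 55)
  G <- build_grm(g)
  perm <- sample(30)
  gp <- subset_individuals(g, perm)
  Gp <- build_grm(gp)
  expect_equal(unclass(Gp), unclass(G)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PSD repair jitters only when needed and lifts negative eigenvalues", {
  g <- random_geno(100, 10, seed = 61)  # 10 variants, 100 individuals: rank-deficient
  K <- build_grm(g)
  Kp <- ensure_psd(K)
  expect_true(chol(unclass(Kp)) |> is.matrix())
  # already-PSD input returns unchanged
  M <- kernel_matrix(diag(5) + 0.1, "G")
  expect_false(attr(ensure_psd(M), "psd_adjusted"))
  # matrix with a known small negative eigenvalue gets repaired
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  bad <- kernel_matrix(Q %*% diag(c(1, 0.5, 0.2, 0.1, -1e-7)) %*% t(Q), "G")
  fixed <- ensure_psd(bad)
  expect_true(attr(fixed, "psd_adjusted"))
  expect_gte(min(eigen(unclass(fixed))$values), -1e-8)
})

test_that("monomorphic panels and mismatched weights are rejected", {
  d <- matrix(2, 5, 3)
  g <- manual_geno(d)
  expect_error(build_grm(g), "monomorphic")
  g2 <- random_geno(10, 5, seed = 2)
  w <- build_weight_vector(rnorm(3), 1:3, 3)
  expect_error(build_weighted_grm(g2, w), "length")
})
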
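test_that("fold assignments partition individuals into near-equal folds", {
  f1 <- make_folds(cv_plan(100, 10, repeats = 2, seed = 1))
  expect_true(all(table(f1[, 1]) == 10))
  f2 <- make_folds(cv_plan(103, 10, repeats = 1, seed = 1))
  sizes <- table(f2[, 1])
  expect_true(all(sizes %in% c(10, 11)))
  expect_equal(sum(sizes), 103)
})

test_that("fold assignments are seed-reproducible and repeat-independent", {
  p <- cv_plan(80, 8, repeats = 3, seed = 5)
  expect_identical(make_folds(p), make_folds(p))
  other <- make_folds(cv_plan(80, 8, repeats = 3, seed = 6))
  expect_false(identical(make_folds(p), other))
  f <- make_folds(p)
  expect_false(identical(f[, 1], f[, 2]))
  expect_error(cv_plan(10, 1), "k_folds")
})

test_that("prediction accuracy is the sample Pearson correlation", {
  set.seed(3)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  # explicit-sums oracle
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / 19
  r_oracle <- cov_xy / sqrt(var(x) * var(y))
  expect_equal(prediction_accuracy(x, y), r_oracle, tolerance = 1e-12)
  expect_equal(prediction_accuracy(x, x), 1)
  expect_equal(prediction_accuracy(x, -x), -1)
  expect_warning(r0 <- prediction_accuracy(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r0))
})

test_that("paired t-test matches the closed form and flags degenerate pairs", {
  b <- c(5, 5, 5)
  a <- b + c(1, 2, 3)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$p, 2 * pt(-2 / (1 / sqrt(3)), df = 2), tolerance = 1e-10)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)

  same <- paired_ttest(c(0.5, 0.6), c(0.5, 0.6))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  shifted <- paired_ttest(c(0.5, 0.6), c(0.4, 0.5))
  expect_true(shifted$degenerate)
  expect_equal(shifted$p, 0)
})

test_that("the CV engine is leakage-safe, deterministic, and model-consistent", {
  cfg <- tiny_config(n_individuals = 100, n_variants = 250, n_qtl = 8,
                     seed = 121)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  ss <- simulate_meta_gwas(cfg, tr$truth)
  yc <- correct_phenotypes(tr$pheno)
  plan <- cv_plan(n_individuals(g), k_folds = 4, repeats = 1, seed = 2)

  # duplicated model specs give identical per-fold accuracies
  cv <- run_cv(g, yc, list(model_spec("BLUPGA", omega = 0.3),
                           model_spec("BLUPGA", omega = 0.3)),
               plan, selections = list(selection_spec("P_top_WGS",
                                                      proportion = 0.1)),
               sumstats = ss)
  accs <- split(cv$accuracy, cumsum(!duplicated(paste(cv$rep, cv$fold))))
  for (a in accs) expect_equal(a[1], a[2])

  # bit-identical rerun under the same seed
  cv2 <- run_cv(g, yc, list(model_spec("BLUPGA", omega = 0.3),
                            model_spec("BLUPGA", omega = 0.3)),
                plan, selections = list(selection_spec("P_top_WGS",
                                                       proportion = 0.1)),
                sumstats = ss)
  expect_identical(cv, cv2)

  # accuracies are correlations
  expect_true(all(cv$accuracy >= -1 & cv$accuracy <= 1))
})

test_that("GBLUP cross-validated accuracy is positive and near the h2 benchmark", {
  accs <- numeric(0)
  for (s in 1:3) {
    cfg <- tiny_config(n_individuals = 250, n_variants = 500,
                       n_qtl = 500, seed = 500 + s)
    g <- simulate_genotypes(cfg)
    tr <- simulate_trait(g, cfg)
    yc <- correct_phenotypes(tr$pheno)
    plan <- cv_plan(n_individuals(g), k_folds = 5, repeats = 1, seed = s)
    cv <- run_cv(g, yc, list(model_spec("GBLUP")), plan)
    accs <- c(accs, cv$accuracy)
  }
  expect_true(all(accs > 0))
  # upper bound: accuracy cannot systematically exceed sqrt(h2)
  expect_lt(mean(accs), sqrt(0.5) + 0.05)
  expect_gt(mean(accs), 0.2)
})

test_that("summaries and comparisons cover every grid cell", {
  cfg <- tiny_config(n_individuals = 90, n_variants = 200, seed = 131)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trait(g, cfg)
  ss <- simulate_meta_gwas(cfg, tr$truth)
  yc <- correct_phenotypes(tr$pheno)
  plan <- cv_plan(n_individuals(g), k_folds = 3, repeats = 2, seed = 4)
  cv <- run_cv(g, yc,
               list(model_spec("GBLUP"), model_spec("TABLUP"),
                    model_spec("BLUPGA", omega = 0.1)),
               plan,
               selections = list(NULL,
                                 selection_spec("P_top_Chip", proportion = 0.1)),
               sumstats = ss)
  summ <- summarize_cv(cv)
  expect_equal(nrow(summ), 4)  # none/GBLUP + 3 models under the selection
  expect_true(all(summ$n_folds == 6))
  comp <- compare_models(cv)
  expect_equal(nrow(comp), 3)  # three model pairs in the selection cell
  expect_true(all(comp$stars %in% c("", "*", "**")))
})
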
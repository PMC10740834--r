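#' Simulate a genotype panel with local LD
#'
#' Generates biallelic dosages as the sum of two haplotypes. Along each
#' chromosome, haplotype alleles follow a first-order Markov chain constructed
#' so that adjacent variants have Pearson correlation `ld_rho` while every
#' variant keeps its own marginal allele frequency (drawn uniformly from
#' `maf_range`): the conditional allele probability at variant j given the
#' allele x at variant j-1 is
#' `p_j + ld_rho * sqrt(p_j (1-p_j) / (p_{j-1} (1-p_{j-1}))) * (x - p_{j-1})`,
#' clamped to \[0, 1\]. This is not a coalescent model; it produces the ranked
#' tag structure that variant preselection needs at desk scale, with analytic
#' control of adjacent-variant r.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (defaults to `config$n_individuals`;
#'   overridden when generating external GWAS cohorts).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param missing_rate Fraction of dosages set missing uniformly at random
#'   (defaults to `config$missing_rate`).
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(config, n = config$n_individuals,
                               seed = config$seed,
                               missing_rate = config$missing_rate) {
  validate_sim_config(config)
  map <- sim_map(config)
  set.seed(seed)
  m <- nrow(map)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  rho <- config$ld_rho
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    p1 <- freqs[idx[1]]
    H[, idx[1]] <- stats::rbinom(2L * n, 1L, p1)
    for (k in seq_along(idx)[-1]) {
      j <- idx[k]; jm <- idx[k - 1]
      pj <- freqs[j]; pm <- freqs[jm]
      slope <- rho * sqrt(pj * (1 - pj) / (pm * (1 - pm)))
      pr <- pmin(1, pmax(0, pj + slope * (H[, jm] - pm)))
      H[, j] <- stats::rbinom(2L * n, 1L, pr)
    }
  }
  dosages <- H[seq_len(n) * 2L - 1L, , drop = FALSE] +
    H[seq_len(n) * 2L, , drop = FALSE]
  storage.mode(dosages) <- "double"
  if (missing_rate > 0) {
    drop <- stats::runif(length(dosages)) < missing_rate
    dosages[drop] <- NA_real_
  }
  rownames(dosages) <- sprintf("ind_%04d", seq_len(n))
  geno_matrix(dosages, map)
}

#' Simulate a trait over a genotype panel
#'
#' Samples `n_qtl` causal variants without replacement, draws raw
#' allele-substitution effects from N(0, `qtl_effect_sd`^2), and rescales them
#' so the realized genetic variance over the panel is exactly `heritability`
#' on a phenotypic-variance-1 scale (residual variance `1 - heritability`).
#' Fixed-effect factor levels (year, season, sex, farm) are assigned uniformly
#' at random and their level effects drawn from N(0, `fixed_effect_sd`^2).
#' The phenotype is `mean + fixed effects + g + e`. True breeding values are
#' the centered QTL dosages (missing entries contribute 0 after centering)
#' times the scaled effects.
#'
#' @param genotypes A [geno_matrix()] for the study population.
#' @param config The [sim_config()] used to generate it.
#' @return A list with `pheno`, a data frame with columns `id`, `trait` and
#'   one column per fixed-effect factor, and `truth`, a `trait_truth` list
#'   with `qtl_indices`, `qtl_effects` (scaled), `true_breeding_values`,
#'   `realized_h2`, `sigma_e2` and the simulated grand `mean`.
#' @export
simulate_trait <- function(genotypes, config) {
  validate_sim_config(config)
  if (config$n_qtl > n_variants(genotypes)) {
    stop2("`n_qtl` exceeds the number of variants in the panel")
  }
  set.seed(config$seed + 1L)
  n <- n_individuals(genotypes)
  h2 <- config$heritability
  grand_mean <- 10

  if (config$n_qtl > 0) {
    qtl <- sort(sample.int(n_variants(genotypes), config$n_qtl))
    eff <- stats::rnorm(config$n_qtl, 0, config$qtl_effect_sd)
    Zq <- impute_mean(genotypes)[, qtl, drop = FALSE]
    Zq <- sweep(Zq, 2, 2 * genotypes$freqs[qtl])
    g_raw <- drop(Zq %*% eff)
    if (h2 > 0) {
      s_raw <- stats::sd(g_raw)
      if (s_raw == 0) stop2("QTL set is monomorphic; cannot reach target heritability")
      scale <- sqrt(h2) / s_raw
    } else {
      scale <- 0
    }
    eff <- eff * scale
    tbv <- g_raw * scale
  } else {
    qtl <- integer(0)
    eff <- numeric(0)
    tbv <- rep(0, n)
  }
  sigma_e2 <- 1 - h2

  factors <- lapply(names(config$fixed_effect_levels), function(f) {
    L <- config$fixed_effect_levels[[f]]
    lev <- sample.int(L, n, replace = TRUE)
    effs <- stats::rnorm(L, 0, config$fixed_effect_sd)
    list(level = factor(paste0(f, lev), levels = paste0(f, seq_len(L))),
         value = effs[lev])
  })
  names(factors) <- names(config$fixed_effect_levels)
  fixed_part <- Reduce(`+`, lapply(factors, `[[`, "value"), rep(0, n))

  e <- if (sigma_e2 > 0) stats::rnorm(n, 0, sqrt(sigma_e2)) else rep(0, n)
  y <- grand_mean + fixed_part + tbv + e

  pheno <- data.frame(id = rownames(genotypes$dosages), trait = y,
                      stringsAsFactors = FALSE)
  for (f in names(factors)) pheno[[f]] <- factors[[f]]$level

  truth <- structure(list(
    qtl_indices = qtl,
    qtl_effects = eff,
    true_breeding_values = tbv,
    realized_h2 = if (h2 > 0) stats::var(tbv) / (stats::var(tbv) + sigma_e2) else 0,
    sigma_e2 = sigma_e2,
    mean = grand_mean
  ), class = "trait_truth")

  list(pheno = pheno, truth = truth)
}

#' Simulate multi-cohort GWAS meta-analysis summary statistics
#'
#' Each cohort receives an independent genotype panel on the same marker map
#' (same config, cohort-specific seed) and a phenotype built from the *same*
#' QTL truth as the study trait plus residual noise (no fixed effects;
#' cohort-level GWAS is assumed to run on pre-corrected phenotypes). Per
#' cohort and variant, a simple linear regression of phenotype on dosage
#' yields an effect estimate and standard error; cohorts are combined by
#' fixed-effect inverse-variance meta-analysis:
#' `w_c = 1/SE_c^2`, `beta = sum(w_c b_c)/sum(w_c)`, `se = sum(w_c)^(-1/2)`,
#' with `z = beta/se` and a two-sided normal p-value.
#'
#' Variants monomorphic in every cohort have no defined SE; they are emitted
#' with `beta = 0`, `p = 1` and `flagged = TRUE`.
#'
#' @param config A [sim_config()] (fields `n_cohorts`, `cohort_sizes`).
#' @param shared_truth The `trait_truth` from [simulate_trait()].
#' @return A `summary_stats` data frame with columns `chr`, `bp`, `a1`
#'   (effect allele), `beta`, `se`, `z`, `p`, `n` (total meta sample size per
#'   variant) and `flagged`.
#' @export
simulate_meta_gwas <- function(config, shared_truth) {
  validate_sim_config(config)
  if (config$n_cohorts < 1) stop2("need at least one cohort")
  map <- sim_map(config)
  m <- nrow(map)
  sum_w <- numeric(m)
  sum_wb <- numeric(m)
  n_tot <- numeric(m)

  B <- matrix(NA_real_, config$n_cohorts, m)
  S <- matrix(NA_real_, config$n_cohorts, m)
  for (ci in seq_len(config$n_cohorts)) {
    nc <- config$cohort_sizes[ci]
    g <- simulate_genotypes(config, n = nc, seed = config$seed + 1000L + ci,
                            missing_rate = 0)
    set.seed(config$seed + 2000L + ci)
    if (length(shared_truth$qtl_indices)) {
      Zq <- sweep(g$dosages[, shared_truth$qtl_indices, drop = FALSE],
                  2, 2 * g$freqs[shared_truth$qtl_indices])
      gval <- drop(Zq %*% shared_truth$qtl_effects)
    } else {
      gval <- rep(0, nc)
    }
    e <- if (shared_truth$sigma_e2 > 0) {
      stats::rnorm(nc, 0, sqrt(shared_truth$sigma_e2))
    } else rep(0, nc)
    reg <- gwas_regression(g$dosages, gval + e)
    B[ci, ] <- reg$beta
    S[ci, ] <- reg$se
  }
  meta <- meta_fixed_effect(B, S, config$cohort_sizes)

  out <- data.frame(
    chr = map$chr, bp = map$bp, a1 = map$a1,
    beta = meta$beta, se = meta$se, z = meta$z, p = meta$p,
    n = meta$n, flagged = meta$flagged,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Per-variant simple linear regression
#'
#' Vectorized ordinary least squares of a phenotype on each variant's dosage
#' separately (slope and its standard error), as a single-cohort GWAS would
#' compute. Monomorphic variants get NA.
#'
#' @param dosages Numeric matrix, individuals x variants (no missing
#'   values).
#' @param y Phenotype vector.
#' @return Data frame with per-variant `beta` and `se`.
#' @export
gwas_regression <- function(dosages, y) {
  n <- length(y)
  if (nrow(dosages) != n) stop2("dimension mismatch")
  if (n < 3) stop2("need at least 3 observations")
  xbar <- colMeans(dosages)
  Sxx <- colSums(dosages^2) - n * xbar^2
  yc <- y - mean(y)
  Sxy <- drop(crossprod(dosages, yc))
  Syy <- sum(yc^2)
  poly <- Sxx > 0
  beta <- ifelse(poly, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / ((n - 2) * Sxx))
  se[!poly | !is.finite(se) | se <= 0] <- NA_real_
  beta[is.na(se)] <- NA_real_
  data.frame(beta = beta, se = se)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort effect estimates with weights `w_c = 1/SE_c^2`:
#' `beta = sum(w_c b_c) / sum(w_c)`, `se = sum(w_c)^(-1/2)`, `z = beta/se`,
#' two-sided normal p-value (clamped to at least 1e-300). Variants with no
#' cohort contributing a defined SE are emitted with `beta = 0`, `p = 1` and
#' `flagged = TRUE`. The pooled SE never exceeds the smallest contributing
#' cohort SE.
#'
#' @param betas,ses Cohorts x variants matrices of estimates and standard
#'   errors (NA where a cohort has no defined estimate).
#' @param cohort_sizes Per-cohort sample sizes, for the per-variant total
#'   `n`.
#' @return List of per-variant vectors `beta`, `se`, `z`, `p`, `n`,
#'   `flagged`.
#' @export
meta_fixed_effect <- function(betas, ses, cohort_sizes) {
  if (!is.matrix(betas)) betas <- matrix(betas, nrow = 1)
  if (!is.matrix(ses)) ses <- matrix(ses, nrow = 1)
  stopifnot(identical(dim(betas), dim(ses)),
            length(cohort_sizes) == nrow(betas))
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  w <- ifelse(ok, 1 / ses^2, 0)
  sum_w <- colSums(w)
  defined <- sum_w > 0
  beta <- ifelse(defined, colSums(ifelse(ok, w * betas, 0)) / sum_w, 0)
  se <- ifelse(defined, 1 / sqrt(sum_w), NA_real_)
  z <- ifelse(defined, beta / se, 0)
  p <- pmax(ifelse(defined, 2 * stats::pnorm(-abs(z)), 1), 1e-300)
  n <- as.integer(colSums(ok * cohort_sizes))
  list(beta = beta, se = se, z = z, p = p, n = n, flagged = !defined)
}
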
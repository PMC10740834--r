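#' Quality-control thresholds
#'
#' Variant filters applied, in order: missingness, minor-allele frequency,
#' Hardy-Weinberg equilibrium, windowed LD pruning. Defaults follow common
#' chip-QC practice: variants are removed when the missing fraction exceeds
#' 0.05 (the conventional reading of a "call rate" filter: call rate below
#' 95%), when MAF < 0.05 (strict; MAF exactly 0.05 is retained), when the HWE
#' chi-square p-value falls below 1e-5, or when the squared dosage
#' correlation with an earlier retained variant within 50 kb exceeds 0.8.
#'
#' @param max_missing_rate Maximum tolerated per-variant missing fraction.
#' @param min_maf Minimum minor-allele frequency (variants with MAF strictly
#'   below are removed).
#' @param hwe_p_min Minimum HWE test p-value.
#' @param ld_r2_max Maximum tolerated squared correlation within the window.
#' @param ld_window_bp Window length in bp for LD pruning.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, min_maf = 0.05,
                          hwe_p_min = 1e-5, ld_r2_max = 0.8,
                          ld_window_bp = 50000) {
  assert_scalar_in(max_missing_rate, 0, 1, "max_missing_rate")
  assert_scalar_in(min_maf, 0, 0.5, "min_maf")
  assert_scalar_in(hwe_p_min, 0, 1, "hwe_p_min")
  assert_scalar_in(ld_r2_max, 0, 1, "ld_r2_max")
  if (ld_window_bp <= 0) stop2("`ld_window_bp` must be positive")
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_p_min = hwe_p_min, ld_r2_max = ld_r2_max,
                 ld_window_bp = ld_window_bp),
            class = "qc_thresholds")
}

qc_report <- function(stage, removed, remaining) {
  data.frame(stage = stage, removed = as.integer(removed),
             remaining = as.integer(remaining), stringsAsFactors = FALSE)
}

#' Filter variants by missingness
#'
#' @param g A [geno_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with the filtered `geno_matrix` and a one-row `report`.
#' @export
filter_missingness <- function(g, thresholds = qc_thresholds()) {
  miss <- colMeans(is.na(g$dosages))
  keep <- miss <= thresholds$max_missing_rate
  list(genotypes = subset_variants(g, keep),
       report = qc_report("missingness", sum(!keep), sum(keep)))
}

#' Filter variants by minor-allele frequency
#'
#' Frequencies are computed from non-missing dosages; variants with
#' `min(p, 1-p) < min_maf` (strict) are removed.
#'
#' @inheritParams filter_missingness
#' @return List with the filtered `geno_matrix` and a one-row `report`.
#' @export
filter_maf <- function(g, thresholds = qc_thresholds()) {
  maf <- pmin(g$freqs, 1 - g$freqs)
  keep <- maf >= thresholds$min_maf
  list(genotypes = subset_variants(g, keep),
       report = qc_report("maf", sum(!keep), sum(keep)))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' the expectations `p^2 : 2pq : q^2` with the allele frequency estimated
#' from the sample. Monomorphic variants have no defined test and pass with
#' p-value 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (dosage 2 / 1 / 0 of the counted
#'   allele).
#' @return The upper-tail chi-square p-value.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # perfect HWE: p = 1
#' hwe_test(0, 100, 0)   # chi-square 100
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop2("need at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Filter variants by Hardy-Weinberg equilibrium
#'
#' @inheritParams filter_missingness
#' @return List with the filtered `geno_matrix` and a one-row `report`.
#' @export
filter_hwe <- function(g, thresholds = qc_thresholds()) {
  pvals <- apply(g$dosages, 2, function(d) {
    d <- d[!is.na(d)]
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
  })
  keep <- pvals >= thresholds$hwe_p_min
  list(genotypes = subset_variants(g, keep),
       report = qc_report("hwe", sum(!keep), sum(keep)))
}

#' Windowed LD pruning
#'
#' Greedy left-to-right scan within each chromosome: for every ordered pair
#' of retained variants within `ld_window_bp`, if the squared Pearson
#' correlation of (mean-imputed) dosages exceeds `ld_r2_max`, the later
#' variant is removed. Deterministic given the input order; zero-variance
#' variants are treated as uncorrelated (r^2 = 0) and so are never removed by
#' this filter.
#'
#' @inheritParams filter_missingness
#' @return List with the pruned `geno_matrix` and a one-row `report`.
#' @export
ld_prune <- function(g, thresholds = qc_thresholds()) {
  d <- impute_mean(g)
  m <- ncol(d)
  keep <- rep(TRUE, m)
  sds <- apply(d, 2, stats::sd)
  for (ch in unique(g$map$chr)) {
    idx <- which(g$map$chr == ch)
    bp <- g$map$bp[idx]
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (!keep[i] || sds[i] == 0) next
      b <- a + 1L
      while (b <= length(idx) && bp[b] - bp[a] <= thresholds$ld_window_bp) {
        j <- idx[b]
        if (keep[j] && sds[j] > 0) {
          r2 <- stats::cor(d[, i], d[, j])^2
          if (is.finite(r2) && r2 > thresholds$ld_r2_max) keep[j] <- FALSE
        }
        b <- b + 1L
      }
    }
  }
  list(genotypes = subset_variants(g, keep),
       report = qc_report("ld_prune", sum(!keep), sum(keep)))
}

#' Run the full QC chain
#'
#' Applies missingness, MAF, HWE and LD-prune filters in that order and
#' accumulates a per-stage report.
#'
#' @inheritParams filter_missingness
#' @return List with the filtered `genotypes` and the stacked `report` data
#'   frame (one row per stage; removed counts sum to input minus output).
#' @export
run_qc <- function(g, thresholds = qc_thresholds()) {
  stages <- list(filter_missingness, filter_maf, filter_hwe, ld_prune)
  reports <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    res <- stages[[k]](g, thresholds)
    g <- res$genotypes
    reports[[k]] <- res$report
  }
  list(genotypes = g, report = do.call(rbind, reports))
}
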
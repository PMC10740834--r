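#' Simulation configuration
#'
#' Describes the synthetic study the generator emulates: a medium-density
#' genotyping panel with local LD, a quantitative trait with year/season/sex/
#' farm fixed effects and a polygenic-plus-major-QTL architecture, and a set
#' of independent GWAS cohorts feeding a fixed-effect meta-analysis. The
#' defaults mirror a desk-scale version of a nucleus-farm pig study: ~500
#' genotyped individuals, a five-chromosome panel, heritability 0.5 with 30
#' major QTLs, fixed-effect factors with 5/2/2/11 levels, and three external
#' GWAS cohorts of 500 individuals each.
#'
#' @param n_individuals Number of individuals in the study (prediction)
#'   population.
#' @param n_variants Total number of biallelic variants across chromosomes.
#' @param n_chromosomes Number of autosomes; variants are split as evenly as
#'   possible.
#' @param chromosome_length_bp Chromosome length in bp; variants are evenly
#'   spaced, so the default (5 Mb with 1000 variants/chromosome) gives 5 kb
#'   spacing and keeps the 50 kb LD-pruning window meaningful.
#' @param maf_range Pair of counted-allele frequencies in (0, 0.5]; each
#'   variant's frequency is drawn uniformly from this interval.
#' @param ld_rho Target Pearson correlation between adjacent variants'
#'   haplotype alleles, in \[0, 1). Controls local LD strength.
#' @param n_qtl Number of causal variants (0 allowed only with zero
#'   heritability).
#' @param qtl_effect_sd Standard deviation of raw QTL allele-substitution
#'   effects before scaling to the target heritability.
#' @param heritability Narrow-sense heritability of the simulated trait, in
#'   \[0, 1\]; genetic values are rescaled so the realized ratio
#'   Var(g)/(Var(g)+sigma_e^2) equals this exactly.
#' @param fixed_effect_levels Named integer vector of level counts for the
#'   fixed-effect factors (year, season, sex, farm).
#' @param fixed_effect_sd Standard deviation of factor-level effects, in
#'   phenotypic-SD units (the phenotypic variance before fixed effects is 1).
#' @param n_cohorts Number of independent GWAS cohorts for the meta-analysis.
#' @param cohort_sizes Integer vector of cohort sample sizes (length
#'   `n_cohorts`).
#' @param missing_rate Fraction of study-panel dosages set missing uniformly
#'   at random, in \[0, 1).
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 100, n_variants = 500, seed = 7)
#' g <- simulate_genotypes(cfg)
sim_config <- function(n_individuals = 500,
                       n_variants = 5000,
                       n_chromosomes = 5,
                       chromosome_length_bp = 5e6,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       n_qtl = 30,
                       qtl_effect_sd = 1,
                       heritability = 0.5,
                       fixed_effect_levels = c(year = 5, season = 2,
                                               sex = 2, farm = 11),
                       fixed_effect_sd = 0.25,
                       n_cohorts = 3,
                       cohort_sizes = rep(500L, n_cohorts),
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    maf_range = as.numeric(maf_range),
    ld_rho = as.numeric(ld_rho),
    n_qtl = as.integer(n_qtl),
    qtl_effect_sd = as.numeric(qtl_effect_sd),
    heritability = as.numeric(heritability),
    fixed_effect_levels = fixed_effect_levels,
    fixed_effect_sd = as.numeric(fixed_effect_sd),
    n_cohorts = as.integer(n_cohorts),
    cohort_sizes = as.integer(cohort_sizes),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 2) stop2("need at least 2 individuals")
  if (cfg$n_variants < 1) stop2("need at least 1 variant")
  if (cfg$n_chromosomes < 1) stop2("need at least 1 chromosome")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop2("`maf_range` must be (low, high) with 0 < low <= high <= 0.5")
  }
  assert_scalar_in(cfg$ld_rho, 0, 1, "ld_rho", hi_open = TRUE)
  assert_scalar_in(cfg$heritability, 0, 1, "heritability")
  if (cfg$n_qtl < 0 || cfg$n_qtl > cfg$n_variants) {
    stop2("`n_qtl` must be between 0 and `n_variants`")
  }
  if (cfg$heritability > 0 && cfg$n_qtl == 0) {
    stop2("positive heritability requires `n_qtl` >= 1")
  }
  assert_scalar_in(cfg$missing_rate, 0, 1, "missing_rate", hi_open = TRUE)
  if (cfg$fixed_effect_sd < 0) stop2("`fixed_effect_sd` must be >= 0")
  if (length(cfg$cohort_sizes) != cfg$n_cohorts) {
    stop2("`cohort_sizes` must have length `n_cohorts`")
  }
  if (cfg$n_cohorts >= 1 && any(cfg$cohort_sizes < 2)) {
    stop2("every cohort needs at least 2 individuals")
  }
  if (is.null(names(cfg$fixed_effect_levels)) ||
      any(cfg$fixed_effect_levels < 1)) {
    stop2("`fixed_effect_levels` must be a named vector of positive counts")
  }
  invisible(cfg)
}

# Deterministic marker map shared by the study panel and all cohorts:
# variants split evenly across chromosomes, evenly spaced positions.
sim_map <- function(cfg) {
  per_chr <- rep(cfg$n_variants %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_variants %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chr <- rep(seq_len(cfg$n_chromosomes), per_chr)
  bp <- unlist(lapply(per_chr, function(m) {
    if (m == 0) return(integer(0))
    spacing <- max(1, floor(cfg$chromosome_length_bp / m))
    as.integer(seq_len(m) * spacing)
  }), use.names = FALSE)
  data.frame(chr = chr, bp = bp, a1 = "A", a2 = "C",
             stringsAsFactors = FALSE)
}
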
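#' Match study variants to external summary statistics by physical position
#'
#' Exact (chromosome, bp) join of the study marker map against a
#' meta-analysis summary-statistics table. When allele labels are available
#' on both sides and the study's counted allele equals the summary table's
#' non-effect allele, the `flip` flag is set so downstream consumers can
#' negate the effect sign. Duplicate positions in the summary table use the
#' first occurrence (with a warning).
#'
#' @param map Study marker map (`chr`, `bp`, optionally `a1`, `a2`).
#' @param stats A `summary_stats` table (`chr`, `bp`, optionally `a1`).
#' @return Data frame with one row per study variant: `matched` (logical),
#'   `stat_row` (index into `stats`, NA when unmatched) and `flip`.
#' @export
match_by_position <- function(map, stats) {
  if (anyDuplicated(stats[c("chr", "bp")])) {
    warning("duplicate positions in summary statistics; using first occurrence",
            call. = FALSE)
  }
  key_map <- paste(map$chr, map$bp, sep = ":")
  key_stat <- paste(stats$chr, stats$bp, sep = ":")
  idx <- match(key_map, key_stat)
  flip <- rep(FALSE, nrow(map))
  if (!is.null(map$a1) && !is.null(stats$a1)) {
    hit <- !is.na(idx)
    flip[hit] <- map$a1[hit] != stats$a1[idx[hit]]
  }
  data.frame(matched = !is.na(idx), stat_row = idx, flip = flip)
}

#' Meta-analysis effects and p-values aligned to a study panel
#'
#' Convenience wrapper over [match_by_position()]: returns the per-variant
#' meta effect (sign-flipped where the counted allele disagrees) and p-value
#' on the study panel, NA for unmatched variants.
#'
#' @inheritParams match_by_position
#' @return Data frame with columns `beta`, `p`, `matched`.
#' @export
align_meta_to_panel <- function(map, stats) {
  pm <- match_by_position(map, stats)
  beta <- p <- rep(NA_real_, nrow(map))
  hit <- pm$matched
  beta[hit] <- stats$beta[pm$stat_row[hit]] * ifelse(pm$flip[hit], -1, 1)
  p[hit] <- stats$p[pm$stat_row[hit]]
  data.frame(beta = beta, p = p, matched = hit)
}

#' Ridge-regression BLUP marker effects
#'
#' Estimates per-variant effects under the ridge/BLUP model with a common
#' prior variance per marker. The shrinkage level comes from single-kernel
#' REML on the corresponding GRM; effects are then obtained by the genomic
#' back-solution, computed in its numerically convenient form
#' `m = (sigma_g^2 / c) Zc' V^-1 (y - mu)` with `V = sigma_g^2 G +
#' sigma_e^2 I` and `c = 2 sum(p_i (1 - p_i))` — algebraically identical to
#' `(1/c) Zc' G^+ g_hat` with `g_hat` the GBLUP breeding values, and to
#' direct ridge regression `(Zc'Zc + lambda I)^-1 Zc' y` with
#' `lambda = c * sigma_e^2 / sigma_g^2`.
#'
#' @param g A [geno_matrix()].
#' @param y Corrected phenotypes: either a numeric vector aligned to the
#'   panel's individuals or a data frame with `id` and `residual` columns.
#' @return List with `effects` (per-variant, trait units per allele dose),
#'   `vc` (the REML fit on G) and `gebv` (fitted breeding values
#'   `Zc %*% effects`). If the genetic variance estimate is (numerically)
#'   zero, all effects are zero with a warning.
#' @export
rrblup_effects <- function(g, y) {
  y <- align_response(g, y)
  n <- n_individuals(g)
  if (n < 10) stop2("need at least 10 individuals")
  d <- impute_mean(g)
  p <- colMeans(d) / 2
  cdenom <- 2 * sum(p * (1 - p))
  if (cdenom <= 0) stop2("panel is monomorphic")
  Zc <- sweep(d, 2, 2 * p)
  G <- kernel_matrix(tcrossprod(Zc) / cdenom, "G")
  vc <- reml_one_kernel(y, G)
  if (vc$sigma_g2 <= 1e-12 * stats::var(y)) {
    warning("genetic variance estimate is zero; all effects set to 0",
            call. = FALSE)
    eff <- rep(0, n_variants(g))
    return(list(effects = eff, vc = vc, gebv = rep(0, n)))
  }
  V <- vc$sigma_g2 * unclass(G) + diag(vc$sigma_e2, n)
  alpha <- solve(V, y - vc$mu)
  eff <- drop(crossprod(Zc, alpha)) * vc$sigma_g2 / cdenom
  list(effects = eff, vc = vc, gebv = drop(Zc %*% eff))
}

# accept y as vector (panel order) or data.frame(id, residual)
align_response <- function(g, y) {
  ids <- rownames(g$dosages)
  if (is.data.frame(y)) {
    pos <- match(ids, y$id)
    if (anyNA(pos)) stop2("phenotypes missing for some genotyped individuals")
    return(as.numeric(y$residual[pos]))
  }
  if (length(y) != length(ids)) {
    stop2("`y` length does not match the number of individuals")
  }
  as.numeric(y)
}
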
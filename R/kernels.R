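#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Zc Zc' / (2 * sum(p_i (1 - p_i)))` where `Zc` is the dosage matrix
#' centered by twice the counted-allele frequency. Frequencies are computed
#' from the data entering the matrix (the subset, when one is given);
#' residual missing dosages are mean-imputed first, which preserves the
#' frequencies.
#'
#' @param g A [geno_matrix()].
#' @param subset Optional integer/logical index of variants to use (default:
#'   all).
#' @param label Kernel label stored on the result.
#' @return A `kernel_matrix`: an n x n symmetric matrix with individual ids
#'   as dimnames and attributes `label` and `psd_adjusted`.
#' @export
build_grm <- function(g, subset = NULL, label = "G") {
  d <- impute_mean(g)
  if (!is.null(subset)) d <- d[, subset, drop = FALSE]
  if (nrow(d) < 2) stop2("need at least 2 individuals")
  if (ncol(d) < 1) stop2("empty variant subset")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop2("all variants in the subset are monomorphic")
  Zc <- sweep(d, 2, 2 * p)
  K <- tcrossprod(Zc) / denom
  kernel_matrix(K, label)
}

kernel_matrix <- function(K, label, psd_adjusted = FALSE) {
  K <- (K + t(K)) / 2  # enforce exact symmetry against rounding
  structure(K, label = label, psd_adjusted = psd_adjusted,
            class = c("kernel_matrix", class(K)))
}

kernel_ids <- function(K) rownames(K)

#' Per-variant weight vector for weighted relationship matrices
#'
#' Selected variants receive `weight_fn` of their (meta-analysis) marker
#' effect, normalized to mean 1 within the selected set; the remaining
#' variants receive the baseline weight 1. All weights are then rescaled by
#' a common factor so their mean over the panel is exactly 1, which keeps a
#' weighted matrix on the same scale as the plain GRM. Normalizing the
#' selected weights first makes the selected-vs-baseline contrast invariant
#' to the trait's units (a raw squared effect in grams versus
#' phenotypic-SD units would otherwise arbitrarily up- or down-weight the
#' selected set against the baseline). The default weight function is the
#' squared effect (variance scale); absolute value is available as an
#' alternative.
#'
#' @param effects Per-variant marker effects over the panel (NA allowed off
#'   the selected set).
#' @param selected Integer indices of the selected variants.
#' @param panel_size Number of variants in the panel the weights cover.
#' @param weight_fn `"squared"` or `"absolute"`.
#' @return Numeric weight vector with mean 1 and attribute `rescaled = TRUE`.
#'   If every selected effect is zero the weights fall back to uniform with a
#'   warning.
#' @export
build_weight_vector <- function(effects, selected, panel_size,
                                weight_fn = c("squared", "absolute")) {
  weight_fn <- match.arg(weight_fn)
  if (length(effects) != panel_size) {
    stop2("`effects` must have length `panel_size`")
  }
  if (length(selected) == 0) stop2("empty selection")
  if (any(selected < 1 | selected > panel_size)) stop2("selection out of bounds")
  eff_sel <- effects[selected]
  if (anyNA(eff_sel)) stop2("every selected variant needs an effect")
  w_sel <- switch(weight_fn,
                  squared = eff_sel^2,
                  absolute = abs(eff_sel))
  w <- rep(1, panel_size)
  if (all(w_sel == 0)) {
    warning("all selected effects are zero; falling back to uniform weights",
            call. = FALSE)
  } else {
    w[selected] <- w_sel / mean(w_sel)
  }
  w <- w / mean(w)
  attr(w, "rescaled") <- TRUE
  w
}

#' Effect-weighted genomic relationship matrix
#'
#' `K = Zc D Zc' / (2 * sum(p_i (1 - p_i)))` with `D = diag(weights)` over
#' the stated variant set: the full panel for the all-SNP weighted matrix
#' (Sa) or the selected variants only for the selected-SNP matrix (Sf). With
#' identity weights this reduces exactly to [build_grm()].
#'
#' @param g A [geno_matrix()].
#' @param weights A weight vector from [build_weight_vector()], one entry per
#'   variant entering the matrix.
#' @param subset Optional variant index; `weights` must match its length.
#' @param label Kernel label (`"Sa"` for all-variant, `"Sf"` for
#'   selected-variant matrices).
#' @return A `kernel_matrix`.
#' @export
build_weighted_grm <- function(g, weights, subset = NULL, label = "Sa") {
  d <- impute_mean(g)
  if (!is.null(subset)) d <- d[, subset, drop = FALSE]
  if (length(weights) != ncol(d)) {
    stop2("`weights` length must match the number of variants entering the matrix")
  }
  if (is.null(attr(weights, "rescaled"))) {
    stop2("`weights` must come from build_weight_vector() (mean-1 rescaled)")
  }
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop2("all variants in the subset are monomorphic")
  Zc <- sweep(d, 2, 2 * p)
  K <- tcrossprod(Zc %*% diag(sqrt(as.numeric(weights)), ncol(Zc))) / denom
  kernel_matrix(K, label)
}

#' Blend a selected-variant matrix with the plain GRM
#'
#' `T = omega * Sf + (1 - omega) * G`, the trait-specific covariance used by
#' the BLUP-given-architecture model. `omega = 0` recovers G, `omega = 1`
#' recovers Sf.
#'
#' @param Sf,G `kernel_matrix` objects over the same individuals in the same
#'   order.
#' @param omega Blending weight in \[0, 1\].
#' @return A `kernel_matrix` labelled `"T"`.
#' @export
blend_kernels <- function(Sf, G, omega) {
  assert_scalar_in(omega, 0, 1, "omega")
  if (!identical(kernel_ids(Sf), kernel_ids(G))) {
    stop2("kernels cover different individuals (or a different order)")
  }
  kernel_matrix(omega * unclass(Sf) + (1 - omega) * unclass(G), "T")
}

#' Ensure a kernel is numerically positive semi-definite
#'
#' Attempts a Cholesky factorization; on failure, adds `delta * mean(diag)`
#' to the diagonal with `delta` escalating 1e-6, 1e-5, ..., 1e-3 until the
#' factorization succeeds. Rank-deficient matrices from small selected sets
#' routinely need this before REML.
#'
#' @param K A `kernel_matrix`.
#' @return The (possibly jittered) `kernel_matrix`; attribute `psd_adjusted`
#'   records whether jitter was applied.
#' @export
ensure_psd <- function(K) {
  M <- unclass(K)
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M)))) {
    stop2("kernel is not symmetric")
  }
  if (chol_ok(M)) return(K)
  md <- mean(diag(M))
  if (md <= 0) md <- 1
  for (delta in 10^seq(-6, -3)) {
    Mj <- M + diag(delta * md, nrow(M))
    if (chol_ok(Mj)) {
      dimnames(Mj) <- dimnames(M)
      return(kernel_matrix(Mj, attr(K, "label") %||% "K", psd_adjusted = TRUE))
    }
  }
  stop2("kernel is indefinite even after diagonal jitter up to 1e-3")
}

chol_ok <- function(M) {
  !inherits(tryCatch(chol(M), error = function(e) e), "error")
}
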
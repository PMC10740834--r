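#' Genotype matrix container
#'
#' A light container for a dosage panel: an individuals x variants matrix of
#' allele dosages in \{0, 1, 2\} (NA for missing), a marker map with physical
#' positions, and per-variant counted-allele frequencies computed from the
#' non-missing dosages. All relationship matrices and marker-effect models in
#' the package consume this object.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames are the
#'   individual ids), variants in columns. Values must be 0, 1, 2 or NA.
#' @param map Data frame with one row per variant and columns `chr`
#'   (chromosome label), `bp` (1-based physical position), and optionally
#'   `a1`/`a2` (counted and other allele). Must be sorted by (chr, bp) with
#'   unique bp within chromosome.
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `map` and `freqs` (counted-allele frequency per variant).
#' @export
geno_matrix <- function(dosages, map) {
  if (!is.matrix(dosages)) stop2("`dosages` must be a matrix")
  if (nrow(map) != ncol(dosages)) {
    stop2("`map` must have one row per variant column of `dosages`")
  }
  if (!all(c("chr", "bp") %in% names(map))) {
    stop2("`map` needs columns `chr` and `bp`")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop2("dosages must be 0, 1, 2 or NA")
  }
  # map must be position-sorted with unique positions within chromosome
  ord <- order(map$chr, map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    stop2("`map` must be sorted by (chr, bp)")
  }
  if (anyDuplicated(map[c("chr", "bp")])) {
    stop2("duplicate (chr, bp) positions in `map`")
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("ind_", seq_len(nrow(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) stop2("duplicate individual ids")
  colnames(dosages) <- variant_ids(map)
  structure(
    list(dosages = dosages, map = as.data.frame(map),
         freqs = compute_freqs(dosages)),
    class = "geno_matrix"
  )
}

variant_ids <- function(map) paste0(map$chr, "_", map$bp)

#' Counted-allele frequencies from dosages
#'
#' @param dosages Dosage matrix (individuals x variants), NA allowed.
#' @return Per-variant frequency of the counted allele, in \[0, 1\].
#' @keywords internal
compute_freqs <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chr))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.2f%%  MAF range: %.3f-%.3f\n", 100 * miss,
              min(pmin(x$freqs, 1 - x$freqs)), max(pmin(x$freqs, 1 - x$freqs))))
  invisible(x)
}

#' Number of individuals / variants
#' @param g A `geno_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname n_individuals
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Subset a genotype panel by variant
#'
#' @param g A `geno_matrix`.
#' @param keep Logical or integer index over variants.
#' @return A `geno_matrix` restricted to the kept variants; frequencies are
#'   recomputed from the retained data.
#' @export
subset_variants <- function(g, keep) {
  geno_matrix(g$dosages[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
}

#' Subset a genotype panel by individual
#'
#' @param g A `geno_matrix`.
#' @param keep Logical or integer index over individuals.
#' @return A `geno_matrix` restricted to the kept individuals; frequencies
#'   are recomputed from the retained data.
#' @export
subset_individuals <- function(g, keep) {
  geno_matrix(g$dosages[keep, , drop = FALSE], g$map)
}

#' Mean-impute residual missing dosages
#'
#' Replaces each missing dosage by twice the variant's counted-allele
#' frequency, which leaves the per-variant frequency unchanged. Intended for
#' the residual missingness left after quality control, immediately before
#' relationship-matrix algebra.
#'
#' @param g A `geno_matrix`.
#' @return A numeric matrix of dosages with no missing values (not a
#'   `geno_matrix`: imputed values are fractional).
#' @export
impute_mean <- function(g) {
  d <- g$dosages
  na <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na)) d[na] <- (2 * g$freqs)[na[, 2]]
  d
}
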
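#' Number of variants in a top proportion
#'
#' `round(proportion * total)` with ties rounded half away from zero and a
#' minimum of one variant. This counting rule reproduces published top-SNP
#' count tables cell by cell (e.g. 1% of 38,242 -> 382; 1% of 854,089 ->
#' 8541; 5% of 857,969 -> 42,898).
#'
#' @param proportion Fraction in (0, 1].
#' @param total Panel size (>= 1).
#' @return Integer count.
#' @export
top_k_count <- function(proportion, total) {
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop2("`proportion` must be in (0, 1]")
  }
  if (total < 1) stop2("`total` must be >= 1")
  max(1L, as.integer(round_half_away(proportion * total)))
}

#' Selection specification
#'
#' One of the four preselection strategies (rank by meta-analysis p-value or
#' by absolute rr-BLUP effect, on a chip- or WGS-density panel), with either
#' a top proportion or a p-value threshold — exactly one of the two.
#'
#' @param strategy `"P_top_Chip"`, `"P_top_WGS"`, `"G_top_Chip"` or
#'   `"G_top_WGS"`.
#' @param proportion Fraction in (0, 1], or NULL.
#' @param pvalue_threshold Probability threshold (strict `p <`), or NULL.
#' @return A `selection_spec` list.
#' @export
selection_spec <- function(strategy = c("P_top_Chip", "P_top_WGS",
                                        "G_top_Chip", "G_top_WGS"),
                           proportion = NULL, pvalue_threshold = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(proportion) == is.null(pvalue_threshold)) {
    stop2("set exactly one of `proportion` / `pvalue_threshold`")
  }
  if (!is.null(proportion)) assert_scalar_in(proportion, 0, 1, "proportion",
                                             lo_open = TRUE)
  if (!is.null(pvalue_threshold)) {
    assert_scalar_in(pvalue_threshold, 0, 1, "pvalue_threshold", lo_open = TRUE)
  }
  structure(list(strategy = strategy, proportion = proportion,
                 pvalue_threshold = pvalue_threshold),
            class = "selection_spec")
}

#' Rank variants for preselection
#'
#' Stable total order of the panel's variants: ascending p-value or
#' descending absolute effect, with ties broken by (chromosome, bp)
#' ascending. Variants with a missing score (e.g. unmatched against the
#' summary statistics) are ranked last.
#'
#' @param scores Per-variant scores (p-values or marker effects; NA allowed).
#' @param map The panel marker map, for the positional tie-break.
#' @param mode `"pvalue_ascending"` or `"abs_effect_descending"`.
#' @return Integer vector of variant indices, best first.
#' @export
rank_variants <- function(scores, map,
                          mode = c("pvalue_ascending", "abs_effect_descending")) {
  mode <- match.arg(mode)
  if (length(scores) != nrow(map)) stop2("`scores` must cover the panel")
  if (any(is.infinite(scores), na.rm = TRUE)) stop2("scores must be finite")
  key <- switch(mode,
                pvalue_ascending = scores,
                abs_effect_descending = -abs(scores))
  order(is.na(key), key, map$chr, map$bp)
}

#' Select the top-ranked variants
#'
#' Proportion mode takes the first `top_k_count(proportion, total)` ranked
#' variants; threshold mode takes every variant with p strictly below the
#' threshold (in rank order) and errors when that set is empty, since a
#' selected-variant kernel over zero variants is undefined.
#'
#' @param ranked Integer ranking from [rank_variants()], covering the panel.
#' @param spec A [selection_spec()].
#' @param pvalues Per-variant p-values (required in threshold mode).
#' @return A `variant_set`: list with ordered `indices`, the `spec` and
#'   `size`.
#' @export
select_top <- function(ranked, spec, pvalues = NULL) {
  total <- length(ranked)
  if (!is.null(spec$proportion)) {
    k <- top_k_count(spec$proportion, total)
    idx <- ranked[seq_len(k)]
  } else {
    if (is.null(pvalues)) stop2("threshold mode needs `pvalues`")
    sel <- !is.na(pvalues) & pvalues < spec$pvalue_threshold
    idx <- ranked[sel[ranked]]
    if (length(idx) == 0) {
      stop2("p-value threshold selects no variants; selected-SNP kernel undefined")
    }
  }
  structure(list(indices = idx, spec = spec, size = length(idx)),
            class = "variant_set")
}
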
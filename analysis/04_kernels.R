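#!/usr/bin/env Rscript
# Step 4: relationship matrices.
#
# Builds the plain GRM (G), the all-variant weighted matrix (Sa), the
# selected-variant matrices (Gf unweighted, Sf weighted; top 5% by meta
# p-value, squared meta effects as weights) and the blended trait-specific
# matrix T = omega*Sf + (1-omega)*G over the omega grid. Writes G and the
# omega = 0.1 blend as TSV and prints scale diagnostics.

library(preselblup)

g <- read_dosage_tsv("results/data/study_panel_qc.tsv")
ss <- read_summary_stats_tsv("results/data/meta_sumstats.tsv")
meta <- align_meta_to_panel(g$map, ss)

ranked <- rank_variants(meta$p, g$map, "pvalue_ascending")
sel <- select_top(ranked, selection_spec("P_top_WGS", proportion = 0.05))
message("selected ", sel$size, " of ", n_variants(g), " variants (top 5%)")

G <- ensure_psd(build_grm(g))
w_all <- build_weight_vector(meta$beta, sel$indices, n_variants(g))
Sa <- ensure_psd(build_weighted_grm(g, w_all, label = "Sa"))
Gf <- ensure_psd(build_grm(g, subset = sel$indices, label = "Gf"))
w_sel <- build_weight_vector(meta$beta[sel$indices], seq_along(sel$indices),
                             sel$size)
Sf <- ensure_psd(build_weighted_grm(g, w_sel, subset = sel$indices,
                                    label = "Sf"))

for (K in list(G, Sa, Gf, Sf)) {
  message(sprintf("%-2s: mean diag %.3f, trace %.1f, psd_adjusted %s",
                  attr(K, "label"), mean(diag(K)), sum(diag(K)),
                  attr(K, "psd_adjusted")))
}

dir.create("results/kernels", showWarnings = FALSE, recursive = TRUE)
write_kernel_tsv(G, "results/kernels/G.tsv")
for (omega in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  Tm <- blend_kernels(Sf, G, omega)
  if (omega == 0.1) write_kernel_tsv(Tm, "results/kernels/T_omega0.1.tsv")
  message(sprintf("T(omega=%.1f): mean diag %.3f", omega, mean(diag(Tm))))
}
message("wrote results/kernels/{G.tsv, T_omega0.1.tsv}")
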
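#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Emulates the design of a nucleus-farm genomic-selection study: a genotyped
# study population (500 individuals x 5000 variants with local LD), one
# quantitative trait (h2 = 0.5, 30 major QTLs) recorded with year/season/
# sex/farm fixed effects, and an external GWAS meta-analysis over three
# independent cohorts of 500 on the same variant map. Everything downstream
# (02-06) reads the files this script writes under results/data/.

library(preselblup)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 2026)

message("simulating genotypes (", cfg$n_individuals, " x ", cfg$n_variants, ")")
g <- simulate_genotypes(cfg)
tr <- simulate_trait(g, cfg)
message("simulating ", cfg$n_cohorts, "-cohort GWAS meta-analysis")
ss <- simulate_meta_gwas(cfg, tr$truth)

write_dosage_tsv(g, "results/data/study_panel.tsv")
write_phenotypes_csv(tr$pheno, "results/data/phenotypes.csv")
write_summary_stats_tsv(ss, "results/data/meta_sumstats.tsv")
write.table(data.frame(qtl_index = tr$truth$qtl_indices,
                       effect = tr$truth$qtl_effects),
            "results/data/true_qtls.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

# trait description, in the style of a summary-statistics table
ds <- descriptive_stats(tr$pheno$trait)
message(sprintf(
  "trait: n = %d, range %.2f-%.2f, mean %.3f, SD %.3f, CV %.1f%%",
  ds$n, ds$min, ds$max, ds$mean, ds$sd, ds$cv))
message(sprintf("realized heritability: %.3f", tr$truth$realized_h2))
message(sprintf("meta-analysis: %d variants, %d with p < 0.01 (%.1f%%)",
                nrow(ss), sum(ss$p < 0.01), 100 * mean(ss$p < 0.01)))
message("wrote results/data/{study_panel.tsv, phenotypes.csv, meta_sumstats.tsv, true_qtls.tsv}")
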
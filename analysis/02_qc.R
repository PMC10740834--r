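#!/usr/bin/env Rscript
# Step 2: genotype quality control.
#
# Applies the variant filters in the standard order -- missingness > 5%,
# MAF < 5%, Hardy-Weinberg p < 1e-5, then windowed LD pruning (r2 > 0.8
# within 50 kb) -- and writes the filtered panel plus a per-stage report.

library(preselblup)

g <- read_dosage_tsv("results/data/study_panel.tsv")
message("input: ", n_individuals(g), " individuals x ", n_variants(g),
        " variants")

qc <- run_qc(g, qc_thresholds())
print(qc$report)

write_dosage_tsv(qc$genotypes, "results/data/study_panel_qc.tsv")
write.table(qc$report, "results/qc_report.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("surviving: ", n_variants(qc$genotypes), " variants -> ",
        "results/data/study_panel_qc.tsv")
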
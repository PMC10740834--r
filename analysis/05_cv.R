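#!/usr/bin/env Rscript
# Step 5: cross-validated prediction over the full grid.
#
# Evaluates the five models under p-value-ranked (P_top_WGS) and
# |rr-BLUP effect|-ranked (G_top_WGS) preselection across a proportion
# grid, by 2 x 5-fold cross-validation. The no-preselection GBLUP baseline
# is included. G_top rankings are refit from the training folds only;
# P_top rankings come from the external meta-analysis and are fold-free.
# Expect a few minutes of runtime.

library(preselblup)

g <- read_dosage_tsv("results/data/study_panel_qc.tsv")
ss <- read_summary_stats_tsv("results/data/meta_sumstats.tsv")
yc <- read.csv("results/data/corrected_phenotypes.csv")

props <- c(0.01, 0.05, 0.2, 1.0)
selections <- c(
  list(NULL),
  lapply(props, function(p) selection_spec("P_top_WGS", proportion = p)),
  lapply(c(0.01, 0.05), function(p) selection_spec("G_top_WGS", proportion = p))
)
models <- list(
  model_spec("GBLUP"),
  model_spec("BLUPGA", omega = 0.1),
  model_spec("BLUPGA", omega = 0.5),
  model_spec("TABLUP"),
  model_spec("GFBLUP"),
  model_spec("GTBLUP")
)
plan <- cv_plan(n_individuals(g), k_folds = 5, repeats = 2, seed = 2026)

message("running ", length(selections), " scenarios x ", length(models),
        " models x ", plan$repeats * plan$k_folds, " folds")
t0 <- Sys.time()
cv <- run_cv(g, yc, models, plan, selections = selections, sumstats = ss)
message("done in ", format(round(difftime(Sys.time(), t0), 1)))

summ <- summarize_cv(cv)
write.table(cv, "results/cv_results.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(summ, "results/cv_summary.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(summ[, c("strategy", "proportion", "model", "omega", "mean_accuracy",
               "sd_accuracy")], row.names = FALSE, digits = 3)

# accuracy-vs-proportion figure (the rising-then-declining pattern)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  dat <- summ[summ$strategy != "none" & summ$model != "GBLUP", ]
  dat$model_lab <- ifelse(dat$model == "BLUPGA",
                          paste0("BLUP|GA (w=", dat$omega, ")"), dat$model)
  baseline <- summ$mean_accuracy[summ$strategy == "none"][1]
  p <- ggplot(dat, aes(proportion, mean_accuracy, colour = model_lab)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = baseline, linetype = "dashed") +
    scale_x_log10() +
    facet_wrap(~strategy) +
    labs(x = "proportion of selected top variants",
         y = "prediction accuracy (Pearson r)",
         colour = NULL,
         caption = "dashed line: GBLUP on all variants") +
    theme_bw()
  ggsave("results/figures/accuracy_vs_proportion.pdf", p,
         width = 8, height = 4)
  message("wrote results/figures/accuracy_vs_proportion.pdf")
}
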
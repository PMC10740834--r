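#!/usr/bin/env Rscript
# Step 6: paired model comparisons.
#
# Within every (strategy, proportion) cell of the CV grid, compares each
# model pair by a paired t-test over the fold accuracies (pairs matched by
# repeat and fold). Stars: * p < 0.05, ** p < 0.01, no multiple-testing
# correction.

library(preselblup)

cv <- read.table("results/cv_results.tsv", header = TRUE, sep = "\t")
class(cv) <- c("cv_result", "data.frame")

comp <- compare_models(cv)
comp <- comp[order(comp$strategy, comp$proportion, comp$p), ]
write.table(comp, "results/model_comparison.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sig <- comp[!is.na(comp$p) & comp$p < 0.05, ]
message(nrow(comp), " model pairs compared; ", nrow(sig),
        " significant at p < 0.05")
print(head(comp[, c("strategy", "proportion", "model_a", "model_b",
                    "mean_diff", "t", "p", "stars")], 20),
      row.names = FALSE, digits = 3)
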
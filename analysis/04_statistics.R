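#!/usr/bin/env Rscript
# Step 4: AMC-vs-MI group comparisons.
#
# Welch's t-test per parameter/region/week on the animal-level values,
# Holm-Sidak adjusted within the four weekly comparisons of each
# parameter/region family, with Cohen's d effect sizes and star notation.

suppressMessages(library(cardiofluor))

animals <- utils::read.csv("results/animals.csv")
comparisons <- compare_groups(animals)
dir.create("results", showWarnings = FALSE)
utils::write.csv(comparisons, "results/comparisons.csv", row.names = FALSE)

sig <- comparisons[comparisons$stars != "ns", ]
cat(sprintf("%d of %d comparisons significant after Holm-Sidak adjustment:\n",
            nrow(sig), nrow(comparisons)))
print(sig[, c("parameter", "roi", "week", "t_stat", "p_adj", "cohen_d",
              "stars")], digits = 3)
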
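#!/usr/bin/env Rscript
# Stage 5: test-retest reliability.
#
# Two-way-ANOVA consistency ICC of each graph measure across the three
# runs, separately for controls and for the pooled patient groups, with
# the poor/fair/moderate/good/excellent rating bands.

library(vnsnet)

per_run <- read.delim("results/features_per_run.tsv")
tab <- icc_table(per_run)
write.table(tab, "results/reliability_icc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("ICC over %d measure x band x group cells: mean %.2f, median %.2f\n",
            nrow(tab), mean(tab$icc), median(tab$icc)))
cat("Rating counts:\n")
print(table(tab$rating))
print(tab, row.names = FALSE)
cat("Wrote results/reliability_icc.tsv\n")
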
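#!/usr/bin/env Rscript
# Stage 3: group statistics.
#
# For each of the nine features (3 measures x 3 bands): bootstrap
# non-parametric two-way ANOVA over responding x sedation in the patient
# groups (10,000 resamples), BH-FDR correction across the nine features,
# and rank tests of controls against each patient group.

library(vnsnet)

averaged <- read.delim("results/features_averaged.tsv")
tab <- group_stats_table(averaged, n_boot = 10000L, seed = 11L)
write.table(tab, "results/group_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- tab[tab$p_vns_fdr < 0.05, c("measure", "band", "p_vns", "p_vns_fdr")]
cat("Features separating responders from non-responders (FDR < 0.05):\n")
print(sig, row.names = FALSE)
cat("\nSedation effect p-values (uncorrected):",
    paste(sprintf("%.2f", tab$p_sedation), collapse = " "), "\n")
cat("Controls vs patients rank tests significant (FDR < 0.05):",
    sum(tab$p_ctrl_vs_resp_fdr < 0.05), "of 9 (responders),",
    sum(tab$p_ctrl_vs_nonresp_fdr < 0.05), "of 9 (non-responders)\n")
cat("Wrote results/group_stats.tsv\n")
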
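#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds the synthetic three-group rs-MEG cohort (9 non-responders, 14
# responders, 14 controls; 3 runs each) at the package's scaled-down
# acquisition settings, plus the twin pedigree used by the heritability
# stage (19 MZ + 13 DZ pairs + 25 singletons = 89 individuals). Everything
# downstream regenerates runs from the seeds recorded here.

library(vnsnet)

seed <- 42L
out <- "results"
dir.create(out, showWarnings = FALSE)

spec <- cohort_spec(n_channels = 16L, run_length_s = 36,
                    control_run_length_s = 36, fs_hz = 127.15,
                    seed = seed)
cohort <- generate_cohort(spec)
write.table(cohort$manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ped <- generate_twin_traits(pedigree_spec(seed = seed))$pedigree
write.table(ped, file.path(out, "pedigree.fam.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Cohort:", nrow(cohort$manifest), "subjects (",
    paste(names(table(cohort$manifest$group)),
          table(cohort$manifest$group), collapse = ", "), ")\n")
cat("Sedated patients:",
    sum(cohort$manifest$sedation), "of",
    sum(cohort$manifest$group != "control"), "\n")
cat("Twin pedigree:", nrow(ped), "individuals,",
    sum(ped$zygosity == "MZ") / 2, "MZ pairs,",
    sum(ped$zygosity == "DZ") / 2, "DZ pairs\n")
cat("Wrote", file.path(out, "manifest.tsv"), "and",
    file.path(out, "pedigree.fam.tsv"), "\n")
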
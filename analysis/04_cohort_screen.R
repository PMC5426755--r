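#!/usr/bin/env Rscript
# Step 4 — breed cohort screening statistics.
#
# Carrier and allele frequencies with 95% Wilson intervals per cohort,
# Hardy-Weinberg expected homozygote frequencies, and the breed-specificity
# verdict (is the allele absent from every non-index cohort?).
#
# Usage: Rscript analysis/04_cohort_screen.R   (after 01_simulate_study.R)

suppressPackageStartupMessages(library(rdebscreen))

cohorts <- read_cohorts("results/dataset/cohorts.tsv")
summary <- screen_summary(cohorts, index_label = cohorts$label[1L])
print(summary)
write_screen_summary(summary, "results/cohort_summary.tsv")
cat("Summary -> results/cohort_summary.tsv\n")
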
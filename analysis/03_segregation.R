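#!/usr/bin/env Rscript
# Step 3 — check segregation of the candidate variant through the litter.
#
# Under fully penetrant autosomal recessive inheritance every affected
# individual must be homozygous alternate, no unaffected individual may
# be, parents of affecteds are obligate carriers, and parent/offspring
# genotypes must be Mendelian-compatible.
#
# Usage: Rscript analysis/03_segregation.R   (after 01_simulate_study.R)

suppressPackageStartupMessages(library(rdebscreen))

ds <- "results/dataset"
ped <- read_pedigree(file.path(ds, "pedigree.ped"))
pv <- read_vcf(file.path(ds, "pedigree.vcf"))
genotypes <- setNames(pv$genotypes[1L, ], colnames(pv$genotypes))

report <- check_recessive_segregation(ped, genotypes)
print(report)
write_segregation_report(report, "results/segregation.tsv")
cat("Report -> results/segregation.tsv\n")
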
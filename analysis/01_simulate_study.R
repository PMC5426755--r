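#!/usr/bin/env Rscript
# Step 1 — generate the synthetic discovery study.
#
# Emulates the study design: one affected genome, 31 control genomes with
# shared background variation, a litter of eight born to carrier parents,
# and a breed screening table. The causal gene is a 1600-codon, 10-exon
# model with an arginine (CGA) codon at 1527, so the planted variant is
# exactly c.4579C>T / p.R1527*.
#
# Usage: Rscript analysis/01_simulate_study.R [seed]

suppressPackageStartupMessages(library(rdebscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1L) as.integer(args[[1L]]) else 1L

outdir <- "results/dataset"
cfg <- sim_config(seed = seed)
d <- emit_dataset(cfg, outdir)

cat("Synthetic study written to", outdir, "\n")
cat("Planted causal variant:\n")
print(d$causal)
cat("Truth record:\n")
print(d$truth, row.names = FALSE)
cat(sprintf("Litter: %d offspring, %d affected\n",
            cfg$litter_size,
            sum(d$pedigree$phenotype == "affected")))
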
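# rdebscreen

Recessive-model variant discovery and carrier screening, packaged as a
reproducible R pipeline. The motivating study system is severe recessive
dystrophic epidermolysis bullosa (RDEB) in Central Asian Shepherd dogs — a
blistering skin disorder caused by a homozygous *COL7A1* stop-gain
(`c.4579C>T`, `p.R1527*`) — but every component is generic over any fully
penetrant autosomal recessive disorder mapped from one affected genome.

The package is aimed at veterinary and comparative genetics groups doing
single-case Mendelian discovery: it implements the analysis that runs
*after* variant calling, on plain VCF/FASTA/GFF3/PED inputs.

## What it computes

1. **Filter funnel** (`run_funnel`): all called sites → case-homozygous
   (`HOM_ALT` in the affected genome) → absent as homozygote from every
   control genome (recessive model; a strict any-allele policy is also
   available) → CDS-overlapping → in a known-gene panel. Per-stage
   survivor counts plus the final candidate table.
2. **Consequence annotation** (`annotate_variant`): strand-aware mapping
   of a substitution to spliced CDS coordinates, codon
   `⌊(c−1)/3⌋ + 1` and offset `((c−1) mod 3) + 1`, amino-acid change
   under the standard genetic code, classification (synonymous /
   missense / nonsense / stop_lost / start_lost), and HGVS `c.` / `p.`
   strings.
3. **Segregation** (`check_recessive_segregation`): complete-segregation
   check under full penetrance, with obligate-carrier and
   Mendelian-impossibility rules and a genotype-by-phenotype table.
4. **Cohort screening** (`screen_summary`): carrier frequency
   (heterozygotes / genotyped), allele frequency, 95% Wilson score
   intervals, Hardy–Weinberg expected homozygote frequency, and a
   breed-specificity verdict.
5. **Synthetic study generator** (`sim_config` / `emit_dataset`): a
   deterministic, seeded study — genome fragment, multi-exon gene models,
   planted CGA→TGA nonsense variant, carrier×carrier litter, 31 control
   genomes, cohort table — with a truth record, used by the test suite
   and the analysis scripts.

## Worked example

The four scripts under `analysis/` run the whole study; `01` writes the
dataset under `results/dataset/`, the rest consume it.

```sh
Rscript analysis/01_simulate_study.R 1
Rscript analysis/02_filter_funnel.R
Rscript analysis/03_segregation.R
Rscript analysis/04_cohort_screen.R
```

Step 2 prints the funnel (seed 1):

```
Recessive-model filter funnel
  total                 501
  case_homozygous        55
  control_exclusion       3
  coding                  3
  panel                   2
2 candidate variant(s)
  chrom   pos ref alt   gene transcript_id     effect    hgvs_c   hgvs_p
1 chr20   651   G   A GENE01     GENE01.t1 synonymous c.4725C>T p.R1575R
2 chr20 22028   C   T COL7A1     COL7A1.t1   nonsense c.4579C>T p.R1527*
```

Reading: of 501 simulated sites, 55 are homozygous in the case, 3 of
those appear in no control as a homozygote, 3 touch a CDS, and 2 fall in
panel genes — the planted *COL7A1* nonsense variant (annotated
`c.4579C>T` / `p.R1527*`, exactly the coordinates of its real
counterpart) plus one synonymous background passenger that a reviewer
would discard on effect class. Step 3 reports `segregates: true` with
the affected offspring homozygous and both parents carriers, and step 4
prints the screening table, e.g. the index breed row:

```
 Central Asian Shepherd Dog   47   13   2   0.2766   27.7%   0.1694   0.41759   0.1809   0.03271
non-index individuals screened: 143
verdict: breed-specific
```

i.e. a 27.7% carrier frequency (95% CI 16.9–41.8%) in the index breed
and zero carrier alleles among the 143 dogs of five related breeds.

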
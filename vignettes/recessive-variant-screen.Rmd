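---
title: "Methods: recessive-model variant discovery and carrier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive-model variant discovery and carrier screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdebscreen)
```

## The problem

A fully penetrant autosomal recessive Mendelian disorder — the motivating
case is severe dystrophic epidermolysis bullosa (RDEB) in Central Asian
Shepherd dogs, caused by a homozygous *COL7A1* stop-gain — can be mapped
from a single affected genome when three independent lines of evidence
line up:

1. **Case/control filtering.** The causal variant must be homozygous in
   the affected animal and must not appear as a homozygote in any healthy
   control genome. A staged filter funnel reduces millions of called
   variants to a handful of candidates.
2. **Segregation.** In the family of the affected animal, genotypes must
   co-travel with the phenotype exactly as the recessive model predicts.
3. **Population screening.** In the breed the allele should be present at
   a plausible carrier frequency; in related breeds it should be absent.

`rdebscreen` implements each step as tested, composable functions, and
ships a synthetic-study generator so the whole pipeline can be exercised
end to end with a known truth. The `analysis/` scripts at the repository
root run the four steps in order.

## The filter funnel

Stages run in a fixed order, with survivor counts recorded after each:

| stage | rule |
|---|---|
| `total` | all biallelic sites after multi-allelic splitting |
| `case_homozygous` | case genotype is `HOM_ALT`; `HET` and `MISSING` fail (the model requires an *observed* homozygote) |
| `control_exclusion` | default policy: drop a site iff ≥1 control is `HOM_ALT` for the same alternate allele; strict policy: any alternate allele in a control drops it |
| `coding` | ≥1 CDS-overlapping annotation; optionally restricted to protein-altering classes |
| `panel` | most severe annotation's gene symbol is in the known-gene panel (skipped when no panel is given) |

Two control policies exist because both readings of "filtered under a
recessive model" are defensible: within-breed controls may legitimately be
unaffected carriers (default, permissive policy), while unrelated
cross-breed controls are unlikely to carry the allele at all (strict
policy). `MISSING` control genotypes never exclude a site — absence of
evidence is not evidence of the allele's absence. The default coding
scope keeps synonymous variants (`any_cds_overlap`): whether a "coding"
count should include synonymous changes is a genuine judgement call, so
both scopes are exposed in `filter_config()`.

Counts are monotonically non-increasing by construction; the candidate
list length always equals the last stage count; permuting the input only
permutes the candidates. These invariants are property-tested.

## Consequence annotation and HGVS rendering

c. coordinates count spliced CDS bases from the first base of the start
codon. For a plus-strand transcript the mapping walks CDS exons in
ascending genomic order; for a minus-strand transcript it starts at the
highest CDS coordinate and walks down, complementing bases onto the
coding strand. The codon arithmetic is

$$\text{codon} = \left\lfloor \frac{c-1}{3} \right\rfloor + 1,\qquad
\text{offset} = ((c-1) \bmod 3) + 1,$$

so CDS position 4579 falls on the first base of codon 1527, and a CGA→TGA
change there renders as `c.4579C>T` / `p.R1527*` (one-letter amino-acid
codes, `*` for stop). Classification rules: identical amino acids are
synonymous; an alternate stop **before** the natural terminator is
nonsense (an alternate stop *at* the terminator is not premature); a lost
reference stop is `stop_lost`; a changed initiator methionine is
`start_lost`; everything else is missense. When a variant overlaps
several transcripts all annotations are returned and filtering uses the
most severe (nonsense > stop_lost > start_lost > missense > coding_other
> synonymous).

Deliberate scope limits: the standard genetic code only (the motivating
variants are nuclear); UTR/intronic HGVS offsets (`c.-`, `c.*`, `c.+`)
are not produced — such variants simply don't annotate; indels in CDS are
carried through filtering as `coding_other` but get no frameshift p.
nomenclature. Reference-allele mismatches between the VCF and the FASTA
are hard data-integrity errors, as are chromosome-name mismatches
(matching is exact string equality; no `chr` normalization).

The annotation path (per-position coordinate arithmetic) is checked in
the test suite against an independent brute-force oracle that splices the
whole CDS with Biostrings, chunks it into triplets and translates each —
two different routes to the same answer.

## Segregation checking

`check_recessive_segregation()` assumes full penetrance, which fits a
disorder with onset at birth: an unaffected homozygote is a model
violation, not a penetrance observation, and no tolerant mode is
provided. Four rules are checked — affected must be `HOM_ALT`; unaffected
must not be; a parent of an affected individual may not be `HOM_REF`
(obligate carrier); and parent/offspring pairs may not be
Mendelian-impossible (`HOM_ALT` child of a `HOM_REF` parent or vice
versa). Only genotyped individuals are constrained, so family members
without samples never block a "complete segregation" verdict;
unknown-phenotype individuals still participate in the Mendelian checks.
The shipped litter fixture genotypes all six unaffected littermates as
carriers; real studies often genotype only a subset, in which case the
check simply constrains fewer individuals.

## Cohort statistics

For each screened cohort the summary reports the carrier frequency
(heterozygotes / genotyped — affected homozygotes are *not* carriers,
which is what makes 13 carriers among 47 dogs 27.7% even when two of the
47 are affected), the allele frequency $(n_{het} + 2 n_{hom}) / 2n$, a
95% Wilson score interval on the carrier frequency, and the
Hardy–Weinberg expected homozygote frequency $q^2$. Wilson rather than
Wald intervals because the screening situation is exactly where Wald
fails: at 0 carriers the Wilson lower bound is exactly 0 and the interval
still has sensible width. Percentages print with one decimal, rounding
half away from zero. No hypothesis tests are attached: cohort counts at
this scale do not support a meaningful exact HWE test, so only the HWE
expectation is reported. The breed-specificity verdict is strict: any
alternate allele in any non-index cohort voids it.

## The synthetic study generator

`sim_config()` + `emit_dataset()` produce a fully self-contained study:
a random genome fragment, multi-exon gene models (every CDS starts ATG,
ends with a stop, has no internal stop), a planted CGA→TGA nonsense
variant, a carrier×carrier litter with Mendelian transmission and
phenotypes assigned from genotypes, control genomes sharing background
variation drawn under Hardy–Weinberg, a gene panel, a breed cohort table,
and a truth record written from the construction (not from the annotation
code, so the two can be compared).

Defaults mirror the motivating study's shape and were fixed when the
generator was designed: 1 case and 31 controls; a litter of eight (two
affected expected under the 1:2:1 ratio); a 40 kb chromosome with five
genes of 1600 codons across 10 exons; the causal CGA codon at 1527 so the
planted variant is exactly `c.4579C>T` / `p.R1527*`; 500 background sites
with alt-allele frequencies uniform on (0.05, 0.5); a cohort table cloned
from the published screening counts (47 index-breed dogs including the
two affected homozygotes — consistent with 2 affected + 2 parents + 6
littermates + 37 biobank dogs). A single master seed is split into
per-purpose streams (genome, pedigree, background) so changing the litter
size does not perturb the genome.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium between background sites
(sites are independent), sequencing error and genotype uncertainty
(genotypes are exact), population structure among controls, and repeat or
low-complexity sequence context. The funnel's behaviour on real
whole-genome callsets (millions of sites, relatedness among controls)
is therefore out of reach of these tests; what they do establish is the
correctness of each stage's rule and of the coordinate arithmetic.

Property tests that need many end-to-end replicates (50-seed funnel
soundness, control-count trends) use a scaled-down configuration — a
two-gene 8 kb fragment with 200-codon genes and 120 background sites —
chosen as the smallest dataset that still exercises every stage; the
single-dataset checks use the full default configuration.

## Numerical and degenerate-input choices

* Coordinates are 1-based and fully closed everywhere, matching VCF POS.
* Multi-allelic records are split per alternate allele; in a split
  record, alleles other than the target count as non-target (not
  missing), because the recessive filter only asks about the target
  allele's dosage.
* Phase is discarded on parse; `0|1` and `0/1` are the same state.
* An empty call set flows through the funnel with all-zero counts — an
  empty result is a result, not an error. An empty gene panel, by
  contrast, is an error: it would silently match nothing.
* `wilson_interval()` delegates to `stats::prop.test(correct = FALSE)`
  (whose confidence interval *is* the Wilson score interval) and clips to
  [0, 1]; the test suite re-derives the textbook formula independently.
* Writers emit byte-stable output (sorted records, fixed column order) so
  identical configurations produce identical files.

## Known limitations

Single-nucleotide resolution only for p. nomenclature; no splice-site or
regulatory consequence prediction; no NMD prediction; no genotype
likelihoods; no X-linked or dominant segregation models; no
pedigree-aware allele-frequency correction in cohort statistics. These
are scope decisions, not oversights: each would change the contract of a
stage that is deliberately small and auditable.
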
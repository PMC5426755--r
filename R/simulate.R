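STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the shape of the canine RDEB discovery study: one
#' affected case genome, 31 unrelated control genomes, a litter of eight
#' born to carrier parents, and a causal-gene model at the scale of a large
#' collagen gene — 1600 codons across 10 exons with an arginine (CGA) codon
#' planted at position 1527, so the planted C>T substitution is exactly
#' c.4579C>T / p.R1527*.
#'
#' @param seed Integer master seed. A single pseudo-random stream is split
#'   hierarchically by purpose (genome, pedigree, background), so changing
#'   e.g. `litter_size` does not perturb the genome.
#' @param chrom Chromosome name of the simulated fragment.
#' @param chrom_length Fragment length in bases.
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene CDS exon count per gene.
#' @param cds_codons Codons per CDS, final stop included.
#' @param causal_gene_index Which gene carries the planted variant; that
#'   gene is named `COL7A1`, the others `GENE01`, `GENE02`, ...
#' @param causal_codon_number Interior codon forced to CGA and mutated
#'   CGA->TGA by [plant_causal_variant()].
#' @param causal_strand Strand of the causal gene (`"+"` or `"-"`); other
#'   genes draw strands at random.
#' @param litter_size Offspring count of the simulated mating.
#' @param n_controls Control genome count.
#' @param background_site_count Shared background variant sites.
#' @param background_alt_freq_range Alt-allele frequency range; each site
#'   draws uniformly from it and genotypes follow Hardy-Weinberg.
#' @param n_controls_het_at_causal Controls made heterozygous at the causal
#'   site (default 0, emulating unrelated cross-breed controls; raise it to
#'   exercise the two control policies).
#' @param panel_genes Gene panel used at the funnel's last stage; defaults
#'   to the causal gene plus one simulated decoy and one absent symbol.
#' @param cohorts A [cohort_counts()] table for the screening step;
#'   defaults to [study_cohorts()].
#' @return A list of class `"sim_config"` with derived per-purpose seeds.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chr20",
                       chrom_length = 40000L,
                       n_genes = 5L,
                       exons_per_gene = 10L,
                       cds_codons = 1600L,
                       causal_gene_index = 3L,
                       causal_codon_number = 1527L,
                       causal_strand = "+",
                       litter_size = 8L,
                       n_controls = 31L,
                       background_site_count = 500L,
                       background_alt_freq_range = c(0.05, 0.5),
                       n_controls_het_at_causal = 0L,
                       panel_genes = NULL,
                       cohorts = study_cohorts()) {
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              cds_codons = as.integer(cds_codons),
              causal_gene_index = as.integer(causal_gene_index),
              causal_codon_number = as.integer(causal_codon_number),
              causal_strand = causal_strand,
              litter_size = as.integer(litter_size),
              n_controls = as.integer(n_controls),
              background_site_count = as.integer(background_site_count),
              background_alt_freq_range = background_alt_freq_range,
              n_controls_het_at_causal = as.integer(n_controls_het_at_causal),
              panel_genes = panel_genes,
              cohorts = cohorts)
  stopifnot(cfg$litter_size >= 1L, cfg$n_genes >= 1L,
            cfg$exons_per_gene >= 1L, cfg$n_controls >= 0L,
            cfg$causal_strand %in% c("+", "-"),
            cfg$causal_gene_index >= 1L,
            cfg$causal_gene_index <= cfg$n_genes,
            cfg$n_controls_het_at_causal <= cfg$n_controls)
  if (cfg$causal_codon_number <= 1L ||
      cfg$causal_codon_number >= cfg$cds_codons) {
    stop("causal_codon_number must be interior: 1 < k < cds_codons",
         call. = FALSE)
  }
  gene_symbols <- sprintf("GENE%02d", seq_len(cfg$n_genes))
  gene_symbols[cfg$causal_gene_index] <- "COL7A1"
  cfg$gene_symbols <- gene_symbols
  if (is.null(cfg$panel_genes)) {
    decoy <- setdiff(gene_symbols, "COL7A1")[1L]
    cfg$panel_genes <- c("COL7A1",
                         if (!is.na(decoy)) decoy else NULL,
                         "NOTAGENE1")
  }
  # per-purpose sub-seeds from a single stream
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(cfg$seed)
  sub <- sample.int(2^31 - 2L, 3L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  cfg$genome_seed <- sub[1L]
  cfg$pedigree_seed <- sub[2L]
  cfg$background_seed <- sub[3L]
  class(cfg) <- "sim_config"
  cfg
}

#' The study's breed screening table
#'
#' Genotype counts of the discovery study's cohort screen: 47 Central Asian
#' Shepherd dogs (13 heterozygous carriers and the 2 affected homozygotes —
#' the affected littermates are counted inside the 47) and 143 dogs from
#' five related breeds, none carrying the allele.
#'
#' @return A [cohort_counts()] table with six rows.
#' @export
study_cohorts <- function() {
  cohort_counts(
    label = c("Central Asian Shepherd Dog", "Caucasian Shepherd Dog",
              "South Russian Ovcharka", "Kuvasz", "Slovakian Chuvach",
              "Tibetan Mastiff"),
    n_total = c(47L, 39L, 3L, 6L, 19L, 76L),
    n_het = c(13L, 0L, 0L, 0L, 0L, 0L),
    n_hom_alt = c(2L, 0L, 0L, 0L, 0L, 0L)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all 61 non-stop codons
sense_codons <- function() {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1L, paste, collapse = "")
  setdiff(all3, STOP_CODONS)
}

#' Build the synthetic genome fragment and gene models
#'
#' A random A/C/G/T fragment carrying `n_genes` non-overlapping multi-exon
#' genes. Every CDS starts with ATG, ends with a stop codon, contains no
#' internal stop, and the causal gene's codon `causal_codon_number` is
#' forced to CGA. Deterministic for a fixed config.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector) and `transcripts`
#'   (list of [transcript()], one per gene, in genomic order).
#' @export
build_genome_and_genes <- function(cfg) {
  set.seed(cfg$genome_seed)
  genome <- random_dna(cfg$chrom_length)

  cds_len <- 3L * cfg$cds_codons
  intron_len <- 60L
  gene_span <- cds_len + (cfg$exons_per_gene - 1L) * intron_len
  slot <- cfg$chrom_length %/% cfg$n_genes
  margin <- slot - gene_span
  if (margin < 2L) {
    stop("layout error: chrom_length ", cfg$chrom_length,
         " leaves no room for ", cfg$n_genes, " genes of span ", gene_span,
         call. = FALSE)
  }

  sense <- sense_codons()
  transcripts <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    codons <- c("ATG", sample(sense, cfg$cds_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    if (g == cfg$causal_gene_index) {
      codons[cfg$causal_codon_number] <- "CGA"
    }
    cds <- paste(codons, collapse = "")

    # exon lengths: even split of the CDS with the remainder on the last exon
    base_len <- cds_len %/% cfg$exons_per_gene
    ex_len <- rep(base_len, cfg$exons_per_gene)
    ex_len[cfg$exons_per_gene] <- ex_len[cfg$exons_per_gene] +
      cds_len - sum(ex_len)
    gene_start <- (g - 1L) * slot + sample.int(margin, 1L)
    starts <- gene_start + cumsum(c(0L, utils::head(ex_len, -1L) + intron_len))
    ends <- starts + ex_len - 1L

    strand <- if (g == cfg$causal_gene_index) {
      cfg$causal_strand
    } else {
      sample(c("+", "-"), 1L)
    }
    tr <- transcript(id = paste0(cfg$gene_symbols[g], ".t1"),
                     gene = cfg$gene_symbols[g],
                     chrom = cfg$chrom, strand = strand,
                     cds_exons = data.frame(start = starts, end = ends))

    # write the CDS into the genome: ascending genomic chunks of the
    # genomic-strand CDS sequence
    gseq <- if (strand == "+") cds else revcomp(cds)
    off <- 0L
    for (e in seq_len(cfg$exons_per_gene)) {
      substring(genome, starts[e], ends[e]) <-
        substring(gseq, off + 1L, off + ex_len[e])
      off <- off + ex_len[e]
    }
    transcripts[[g]] <- tr
  }
  genome <- stats::setNames(genome, cfg$chrom)
  list(genome = genome, transcripts = transcripts)
}

#' Plant the causal nonsense variant
#'
#' Returns the single-base substitution at the first base of the causal
#' CGA codon that turns it into TGA (arginine to stop). Genomic ref/alt are
#' C>T on a plus-strand gene and G>A on a minus-strand gene; the coding
#' change is C>T either way.
#'
#' @param genome Named character vector from [build_genome_and_genes()].
#' @param tr The causal [transcript()].
#' @param codon_number Codon to mutate; its reference codon must be CGA.
#' @return A [variant()].
#' @export
plant_causal_variant <- function(genome, tr, codon_number) {
  codon <- reference_codon(tr, codon_number, genome)
  if (codon != "CGA") {
    stop("causal codon ", codon_number, " of ", tr$id, " is ", codon,
         ", not CGA", call. = FALSE)
  }
  gpos <- cds_map(tr)[3L * (codon_number - 1L) + 1L]
  if (tr$strand == "+") {
    variant(tr$chrom, gpos, "C", "T")
  } else {
    variant(tr$chrom, gpos, "G", "A")
  }
}

#' Simulate the litter pedigree and its genotypes
#'
#' Two carrier (HET) parents and `litter_size` offspring, each drawing one
#' allele per parent independently. Phenotypes are assigned under full
#' penetrance: affected iff homozygous alternate. Offspring sexes are
#' uniform.
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree` (a [pedigree()]) and `genotypes` (named
#'   character vector of states).
#' @export
simulate_pedigree_genotypes <- function(cfg) {
  set.seed(cfg$pedigree_seed)
  pups <- sprintf("PUP%d", seq_len(cfg$litter_size))
  alleles <- matrix(stats::rbinom(2L * cfg$litter_size, 1L, 0.5),
                    ncol = 2L)  # one allele per HET parent
  states <- c("HOM_REF", "HET", "HOM_ALT")[rowSums(alleles) + 1L]
  genotypes <- stats::setNames(c("HET", "HET", states),
                               c("SIRE", "DAM", pups))
  ped <- pedigree(data.frame(
    family = "LITTER1",
    id = c("SIRE", "DAM", pups),
    sire = c(NA, NA, rep("SIRE", cfg$litter_size)),
    dam = c(NA, NA, rep("DAM", cfg$litter_size)),
    sex = c("male", "female",
            sample(c("male", "female"), cfg$litter_size, replace = TRUE)),
    phenotype = c("unaffected", "unaffected",
                  ifelse(states == "HOM_ALT", "affected", "unaffected")),
    stringsAsFactors = FALSE
  ))
  list(pedigree = ped, genotypes = genotypes)
}

#' Simulate the case/control call set
#'
#' Draws `background_site_count` shared background variant sites (positions
#' without replacement, excluding the causal position), each with an
#' alt-allele frequency from the configured range and genotypes drawn per
#' individual under Hardy-Weinberg. The causal site is appended with the
#' case homozygous alternate and every control free of the causal allele
#' (except `n_controls_het_at_causal` carriers when configured). Sites are
#' independent across positions: no linkage disequilibrium is modelled.
#'
#' @param cfg A [sim_config()].
#' @param genome Named character vector from [build_genome_and_genes()].
#' @param causal A [variant()] from [plant_causal_variant()].
#' @return A [site_set()] over samples `CASE`, `CTRL01`, ...
#' @export
simulate_background_and_controls <- function(cfg, genome, causal) {
  set.seed(cfg$background_seed)
  L <- nchar(genome[[cfg$chrom]])
  if (cfg$background_site_count > L - 1L) {
    stop("layout error: background_site_count exceeds available positions",
         call. = FALSE)
  }
  pos <- sample(setdiff(seq_len(L), causal$pos), cfg$background_site_count)
  pos <- sort(pos)
  refs <- substring(genome[[cfg$chrom]], pos, pos)
  alts <- vapply(refs, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1L), USE.NAMES = FALSE)

  samples <- c("CASE", sprintf("CTRL%02d", seq_len(cfg$n_controls)))
  lo <- cfg$background_alt_freq_range[1L]
  hi <- cfg$background_alt_freq_range[2L]
  af <- stats::runif(cfg$background_site_count, lo, hi)
  geno <- matrix("HOM_REF", cfg$background_site_count, length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    dosage <- stats::rbinom(cfg$background_site_count, 2L, af)
    geno[, j] <- c("HOM_REF", "HET", "HOM_ALT")[dosage + 1L]
  }

  causal_geno <- rep("HOM_REF", length(samples))
  names(causal_geno) <- samples
  causal_geno["CASE"] <- "HOM_ALT"
  if (cfg$n_controls_het_at_causal > 0L) {
    causal_geno[1L + seq_len(cfg$n_controls_het_at_causal)] <- "HET"
  }

  variants <- rbind(
    data.frame(chrom = cfg$chrom, pos = pos, ref = refs, alt = alts),
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt)
  )
  geno <- rbind(geno, causal_geno)
  ord <- order(variants$pos)
  site_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}

#' Generate and write a complete synthetic study
#'
#' Runs the whole generator and writes every input the downstream pipeline
#' needs, plus a truth record derived from the construction (not from the
#' annotation code, so the two can be compared):
#' `genome.fasta`, `genes.gff3`, `study.vcf` (case + controls),
#' `pedigree.ped`, `pedigree.vcf` (the causal site across the litter),
#' `panel.txt`, `cohorts.tsv`, `truth.tsv`. Re-running with the same config
#' is byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory objects: `genome`,
#'   `transcripts`, `causal`, `sites`, `pedigree`, `ped_genotypes`,
#'   `truth`, and `paths`.
#' @export
emit_dataset <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  gg <- build_genome_and_genes(cfg)
  causal_tr <- gg$transcripts[[cfg$causal_gene_index]]
  causal <- plant_causal_variant(gg$genome, causal_tr,
                                 cfg$causal_codon_number)
  sites <- simulate_background_and_controls(cfg, gg$genome, causal)
  fam <- simulate_pedigree_genotypes(cfg)

  ped_geno <- matrix(fam$genotypes, nrow = 1L,
                     dimnames = list(NULL, names(fam$genotypes)))
  ped_sites <- site_set(
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt),
    ped_geno
  )

  k <- cfg$causal_codon_number
  truth <- data.frame(
    key = c("chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c",
            "hgvs_p", "case_sample"),
    value = c(causal$chrom, causal$pos, causal$ref, causal$alt,
              causal_tr$gene, causal_tr$id,
              sprintf("c.%dC>T", 3L * (k - 1L) + 1L),
              sprintf("p.R%d*", k), "CASE")
  )

  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    gff3 = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "study.vcf"),
    ped = file.path(outdir, "pedigree.ped"),
    ped_vcf = file.path(outdir, "pedigree.vcf"),
    panel = file.path(outdir, "panel.txt"),
    cohorts = file.path(outdir, "cohorts.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_genome(gg$genome, paths$genome)
  write_gene_models(gg$transcripts, paths$gff3)
  write_vcf(sites, paths$vcf)
  write_pedigree(fam$pedigree, paths$ped)
  write_vcf(ped_sites, paths$ped_vcf)
  writeLines(c("# synthetic gene panel", cfg$panel_genes), paths$panel)
  write_cohorts(cfg$cohorts, paths$cohorts)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(genome = gg$genome, transcripts = gg$transcripts,
                 causal = causal, sites = sites,
                 pedigree = fam$pedigree, ped_genotypes = fam$genotypes,
                 truth = truth, paths = paths))
}
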
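# Shared in-code fixtures and independent oracles.

# A 3-codon plus-strand toy gene: CDS "ATG CGA TAA" embedded at 11..19 of a
# 30 bp chromosome. Codon 2 is CGA, so the C>T substitution at genomic 14
# is the miniature analogue of the study's arginine-to-stop change.
toy_plus <- function() {
  genome <- c(chrT = paste0("AAAAACCCCC", "ATGCGATAA", "GGGGGTTTTTT"))
  tr <- transcript("toy.t1", "TOY", "chrT", "+",
                   data.frame(start = 11L, end = 19L))
  list(genome = genome, tr = tr)
}

# The same CDS on the minus strand: the genomic segment holds the reverse
# complement of "ATGCGATAA".
toy_minus <- function() {
  genome <- c(chrT = paste0("AAAAACCCCC", "TTATCGCAT", "GGGGGTTTTTT"))
  tr <- transcript("toy.t1", "TOY", "chrT", "-",
                   data.frame(start = 11L, end = 19L))
  list(genome = genome, tr = tr)
}

# Independent consequence oracle: splice the full CDS with Biostrings,
# reverse-complement for minus-strand transcripts, chunk into triplets and
# translate each. Never calls cds_position/reference_codon.
oracle_spliced_cds <- function(tr, genome) {
  chrom <- Biostrings::DNAString(genome[[tr$chrom]])
  parts <- lapply(seq_len(nrow(tr$cds_exons)), function(i) {
    as.character(Biostrings::subseq(chrom, tr$cds_exons$start[i],
                                    tr$cds_exons$end[i]))
  })
  cds <- paste(unlist(parts), collapse = "")
  if (tr$strand == "-") {
    cds <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

oracle_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

oracle_protein <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# Random transcript plus matching genome fragment: <= 10 exons, CDS <= 999
# bases, random strand, random intron/flank sizes.
random_transcript <- function() {
  n_ex <- sample(1:10, 1L)
  ex_len <- sample(3:34, n_ex, replace = TRUE)
  total <- sum(ex_len)
  total <- total - (total %% 3L)
  if (total < 3L) total <- 3L
  # re-split the rounded total across exons
  cuts <- sort(sample(seq_len(total - 1L), n_ex - 1L))
  ex_len <- diff(c(0L, cuts, total))
  ex_len[ex_len == 0L] <- 1L
  total <- sum(ex_len)
  if (total %% 3L != 0L) {
    ex_len[n_ex] <- ex_len[n_ex] + (3L - total %% 3L)
  }
  introns <- sample(1:20, n_ex, replace = TRUE)[-1L]
  starts <- 5L + cumsum(c(0L, head(ex_len, -1L) + introns))
  ends <- starts + ex_len - 1L
  L <- max(ends) + 5L
  genome <- c(chrR = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""))
  tr <- transcript("rnd.t1", "RND", "chrR",
                   sample(c("+", "-"), 1L),
                   data.frame(start = starts, end = ends))
  list(genome = genome, tr = tr)
}

# Random site_set over a given sample list and chromosome length.
random_site_set <- function(samples, chrom, L, n) {
  pos <- sort(sample(seq_len(L), n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1L), USE.NAMES = FALSE)
  geno <- matrix(sample(GT_STATES, n * length(samples), replace = TRUE),
                 nrow = n, dimnames = list(NULL, samples))
  site_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt), geno)
}

# Random site_set whose ref alleles agree with a genome (annotation-safe).
random_site_set_on_genome <- function(samples, genome, n) {
  chrom <- names(genome)[1L]
  L <- nchar(genome[[chrom]])
  if (n == 0L) {
    return(site_set(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(character(), 0L, length(samples),
             dimnames = list(NULL, samples))))
  }
  pos <- sort(sample(seq_len(L), n))
  ref <- substring(genome[[chrom]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1L), USE.NAMES = FALSE)
  geno <- matrix(sample(GT_STATES, n * length(samples), replace = TRUE,
                        prob = c(0.45, 0.25, 0.25, 0.05)),
                 nrow = n, dimnames = list(NULL, samples))
  site_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt), geno)
}

# Textbook Wilson score interval, written out independently of prop.test.
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# A small config so many-seed end-to-end runs stay quick.
small_sim_config <- function(seed, ...) {
  base <- list(seed = seed, chrom_length = 8000L, n_genes = 2L,
               exons_per_gene = 4L, cds_codons = 200L,
               causal_gene_index = 1L, causal_codon_number = 60L,
               background_site_count = 120L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

litter_fixture_genotypes <- function(vcf_path) {
  pv <- read_vcf(vcf_path)
  setNames(pv$genotypes[1L, ], colnames(pv$genotypes))
}
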
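#' Reverse-complement a DNA string
#' @param x Character DNA string (A/C/G/T/N).
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Genomic positions of the spliced CDS in translation order: ascending
# through exons for "+", descending from the highest coordinate for "-".
cds_map <- function(tr) {
  pos <- unlist(lapply(seq_len(nrow(tr$cds_exons)), function(i) {
    seq.int(tr$cds_exons$start[i], tr$cds_exons$end[i])
  }), use.names = FALSE)
  if (tr$strand == "-") rev(pos) else pos
}

#' Map a genomic position to a CDS (c.) position
#'
#' c. numbering counts spliced CDS bases from the first base of the start
#' codon: on the plus strand the count walks exons in ascending genomic
#' order, on the minus strand it starts at the highest CDS coordinate and
#' walks downward. Positions outside every CDS exon (introns, UTRs,
#' intergenic) get `NA` — UTR/intronic HGVS offset notation is out of scope.
#'
#' @param tr A [transcript()].
#' @param genomic_pos 1-based genomic position.
#' @return Integer c. position in `[1, cds_length(tr)]`, or `NA` if the
#'   position is not in the CDS.
#' @export
cds_position <- function(tr, genomic_pos) {
  stopifnot(genomic_pos >= 1L)
  match(as.integer(genomic_pos), cds_map(tr))
}

#' Codon number and within-codon offset of a CDS position
#'
#' The relation underlying HGVS c. to p. numbering: CDS position 4579 lies
#' in codon 1527 at offset 1, since 4579 = 3 * (1527 - 1) + 1.
#'
#' @param c_pos 1-based CDS position (vectorized).
#' @return `data.frame` with integer columns `codon_number` and
#'   `codon_offset` (offset in 1..3).
#' @export
codon_index <- function(c_pos) {
  c_pos <- as.integer(c_pos)
  if (any(is.na(c_pos)) || any(c_pos < 1L)) {
    stop("c_pos must be >= 1", call. = FALSE)
  }
  data.frame(codon_number = (c_pos - 1L) %/% 3L + 1L,
             codon_offset = (c_pos - 1L) %% 3L + 1L)
}

#' Extract a reference codon from the genome
#'
#' Returns the three CDS bases of the requested codon in translation order;
#' minus-strand codons are complemented base-by-base while the map runs
#' right-to-left, which together amounts to reverse complementation.
#'
#' @param tr A [transcript()].
#' @param codon_number 1-based codon index.
#' @param genome Named character vector from [read_genome()].
#' @return A DNA triplet string.
#' @export
reference_codon <- function(tr, codon_number, genome) {
  n_codons <- cds_length(tr) %/% 3L
  if (codon_number < 1L || codon_number > n_codons) {
    stop("codon_number ", codon_number, " outside 1..", n_codons,
         " for transcript ", tr$id, call. = FALSE)
  }
  chromseq <- genome_chrom(genome, tr$chrom)
  pos <- cds_map(tr)[(3L * (codon_number - 1L) + 1L):(3L * codon_number)]
  bases <- substring(chromseq, pos, pos)
  if (tr$strand == "-") bases <- comp_base(bases)
  paste(bases, collapse = "")
}

genome_chrom <- function(genome, chrom) {
  if (!(chrom %in% names(genome))) {
    stop("chromosome '", chrom, "' not present in the genome (available: ",
         paste(names(genome), collapse = ", "),
         "); chromosome names are matched by exact string equality",
         call. = FALSE)
  }
  genome[[chrom]]
}

#' Translate a codon under the standard genetic code
#'
#' @param triplet DNA triplet (A/C/G/T only; ambiguity codes are an error).
#' @return Single-letter amino acid, `"*"` for stop.
#' @examples
#' translate_codon("CGA") # "R"
#' translate_codon("TGA") # "*"
#' @export
translate_codon <- function(triplet) {
  if (!grepl("^[ACGT]{3}$", triplet)) {
    stop("not a DNA triplet over A/C/G/T: '", triplet, "'", call. = FALSE)
  }
  unname(Biostrings::GENETIC_CODE[[triplet]])
}

#' Classify an amino-acid substitution
#'
#' Stop-gain calls require the affected codon to precede the natural stop:
#' an alt stop at the final codon is a change at the terminator, not a
#' premature one, and falls through to the identity/missense rules.
#'
#' @param ref_aa,alt_aa Single-letter amino acids (`"*"` = stop).
#' @param codon_number 1-based codon index of the change.
#' @param cds_codon_count Total codons in the CDS, including the stop.
#' @return One of `"synonymous"`, `"nonsense"`, `"stop_lost"`,
#'   `"start_lost"`, `"missense"`.
#' @export
classify_substitution <- function(ref_aa, alt_aa, codon_number,
                                  cds_codon_count) {
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*" && codon_number < cds_codon_count) return("nonsense")
  if (ref_aa == "*") return("stop_lost")
  if (codon_number == 1L && ref_aa == "M") return("start_lost")
  "missense"
}

# severity used to pick the representative annotation of a multi-transcript
# variant; smaller = more severe
EFFECT_SEVERITY <- c(nonsense = 1, stop_lost = 2, start_lost = 3,
                     missense = 4, coding_other = 5, synonymous = 6)

empty_annotation <- function() {
  data.frame(transcript_id = character(), gene = character(),
             c_pos = integer(), codon_number = integer(),
             codon_offset = integer(), ref_codon = character(),
             alt_codon = character(), ref_aa = character(),
             alt_aa = character(), effect = character(),
             hgvs_c = character(), hgvs_p = character())
}

#' Annotate a variant against coding transcripts
#'
#' For every transcript whose CDS contains the variant, derives the c.
#' position, affected codon, amino-acid change, consequence class and HGVS
#' c./p. strings. The alternate allele is complemented for minus-strand
#' transcripts, so the HGVS strings are always on the coding strand.
#' Substitutions get full annotation; indels overlapping a CDS are labelled
#' `coding_other` with no codon arithmetic. Variants outside every CDS
#' return a zero-row table.
#'
#' @param v A [variant()].
#' @param transcripts List of [transcript()] objects.
#' @param genome Named character vector from [read_genome()].
#' @return `data.frame` with one row per overlapping transcript: columns
#'   `transcript_id`, `gene`, `c_pos`, `codon_number`, `codon_offset`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`, `hgvs_c`,
#'   `hgvs_p`.
#' @export
annotate_variant <- function(v, transcripts, genome) {
  rows <- lapply(transcripts, function(tr) {
    if (tr$chrom != v$chrom) return(NULL)
    if (!is_substitution(v)) {
      # indel: any overlap of the REF span with the CDS is coding_other
      span <- seq.int(v$pos, v$pos + nchar(v$ref) - 1L)
      hit <- !all(is.na(match(span, cds_map(tr))))
      if (!hit) return(NULL)
      return(data.frame(transcript_id = tr$id, gene = tr$gene,
                        c_pos = NA_integer_, codon_number = NA_integer_,
                        codon_offset = NA_integer_, ref_codon = NA_character_,
                        alt_codon = NA_character_, ref_aa = NA_character_,
                        alt_aa = NA_character_, effect = "coding_other",
                        hgvs_c = NA_character_, hgvs_p = NA_character_))
    }
    c_pos <- cds_position(tr, v$pos)
    if (is.na(c_pos)) return(NULL)
    gbase <- substring(genome_chrom(genome, v$chrom), v$pos, v$pos)
    if (gbase != v$ref) {
      stop("reference mismatch at ", v$chrom, ":", v$pos, ": variant ref '",
           v$ref, "' but genome has '", gbase, "'", call. = FALSE)
    }
    ci <- codon_index(c_pos)
    ref_codon <- reference_codon(tr, ci$codon_number, genome)
    cds_ref <- if (tr$strand == "-") comp_base(v$ref) else v$ref
    cds_alt <- if (tr$strand == "-") comp_base(v$alt) else v$alt
    alt_codon <- ref_codon
    substring(alt_codon, ci$codon_offset, ci$codon_offset) <- cds_alt
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    effect <- classify_substitution(ref_aa, alt_aa, ci$codon_number,
                                    cds_length(tr) %/% 3L)
    data.frame(transcript_id = tr$id, gene = tr$gene, c_pos = c_pos,
               codon_number = ci$codon_number,
               codon_offset = ci$codon_offset,
               ref_codon = ref_codon, alt_codon = alt_codon,
               ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
               hgvs_c = format_hgvs_c(c_pos, cds_ref, cds_alt),
               hgvs_p = sprintf("p.%s%d%s", ref_aa, ci$codon_number, alt_aa))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty_annotation())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Most severe annotation of a variant
#'
#' Severity order: nonsense > stop_lost > start_lost > missense >
#' coding_other > synonymous; ties broken by transcript order.
#'
#' @param ann Annotation table from [annotate_variant()].
#' @return A one-row `data.frame`, or `NULL` for a zero-row input.
#' @export
best_annotation <- function(ann) {
  if (nrow(ann) == 0L) return(NULL)
  ann[which.min(EFFECT_SEVERITY[ann$effect]), , drop = FALSE]
}

#' Format an HGVS c. substitution string
#' @param c_pos 1-based CDS position.
#' @param ref_base,alt_base Single coding-strand bases.
#' @return String of the form `"c.4579C>T"`.
#' @export
format_hgvs_c <- function(c_pos, ref_base, alt_base) {
  stopifnot(grepl("^[ACGT]$", ref_base), grepl("^[ACGT]$", alt_base))
  sprintf("c.%d%s>%s", as.integer(c_pos), ref_base, alt_base)
}

#' Parse an HGVS c. substitution string
#' @param s String matching exactly `"c.<int><base>><base>"`.
#' @return List with `c_pos`, `ref_base`, `alt_base`.
#' @export
parse_hgvs_c <- function(s) {
  m <- regmatches(s, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", s))[[1L]]
  if (length(m) != 4L) {
    stop("not a valid HGVS c. substitution: '", s, "'", call. = FALSE)
  }
  list(c_pos = as.integer(m[2L]), ref_base = m[3L], alt_base = m[4L])
}
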
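#' Read a reference genome fragment from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector, one uppercase sequence per chromosome
#'   (names are the first whitespace-delimited token of each header).
#'   Alphabet is restricted to A/C/G/T/N.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (any(!nzchar(seqs))) stop("empty sequence in ", path, call. = FALSE)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("genome alphabet must be A/C/G/T/N: ", path, call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome names in ", path, call. = FALSE)
  }
  seqs
}

#' Write a genome fragment as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Construct a transcript model
#'
#' Strand-aware CDS exon structure used for c.-coordinate mapping and codon
#' extraction. Exon intervals are stored in genomic order (ascending start,
#' 1-based closed) regardless of strand; translation order for minus-strand
#' transcripts walks them from the highest coordinate downwards.
#'
#' @param id Transcript identifier.
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons `data.frame` with integer columns `start`, `end`.
#' @return A list of class `"transcript"`.
#' @export
transcript <- function(id, gene, chrom, strand, cds_exons) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(cds_exons),
            all(c("start", "end") %in% names(cds_exons)),
            nrow(cds_exons) >= 1L)
  ex <- data.frame(start = as.integer(cds_exons$start),
                   end = as.integer(cds_exons$end))
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  if (any(ex$start > ex$end)) {
    stop("transcript ", id, ": exon start > end", call. = FALSE)
  }
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
    stop("transcript ", id, ": overlapping CDS exons", call. = FALSE)
  }
  len <- sum(ex$end - ex$start + 1L)
  if (len %% 3L != 0L) {
    stop("transcript ", id, ": CDS length ", len, " not divisible by 3",
         call. = FALSE)
  }
  structure(list(id = id, gene = gene, chrom = chrom, strand = strand,
                 cds_exons = ex),
            class = "transcript")
}

#' Total spliced CDS length of a transcript
#' @param tr A [transcript()].
#' @return Integer number of CDS bases.
#' @export
cds_length <- function(tr) {
  sum(tr$cds_exons$end - tr$cds_exons$start + 1L)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s (%s) %s%s, %d CDS exons, %d bp\n",
              x$id, x$gene, x$chrom, x$strand, nrow(x$cds_exons),
              cds_length(x)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Consumes the gene/mRNA/CDS subset: one transcript per mRNA feature, CDS
#' intervals linked by their `Parent` attribute, gene symbol from the gene
#' feature's `Name` (falling back to its `ID`).
#'
#' @param path GFF3 file path.
#' @return List of [transcript()] objects, in mRNA file order.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)

  genes <- which(typ == "gene")
  gene_symbol <- ifelse(is.na(gr$Name[genes]), ids[genes], gr$Name[genes])
  names(gene_symbol) <- ids[genes]

  mrnas <- which(typ == "mRNA")
  if (length(mrnas) == 0L) stop("no mRNA features in ", path, call. = FALSE)
  cds <- which(typ == "CDS")
  cds_parent <- vapply(gr$Parent[cds], function(p) {
    if (length(p) != 1L) {
      stop("CDS feature without a single Parent in ", path, call. = FALSE)
    }
    p
  }, character(1L))

  lapply(mrnas, function(i) {
    mid <- ids[i]
    gparent <- as.character(gr$Parent[[i]])
    sym <- if (length(gparent) == 1L && gparent %in% names(gene_symbol)) {
      gene_symbol[[gparent]]
    } else {
      mid
    }
    mine <- cds[cds_parent == mid]
    if (length(mine) == 0L) {
      stop("mRNA ", mid, " has no CDS features (broken Parent linkage?)",
           call. = FALSE)
    }
    transcript(
      id = mid, gene = sym,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      cds_exons = data.frame(start = GenomicRanges::start(gr)[mine],
                             end = GenomicRanges::end(gr)[mine])
    )
  })
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS rows with ID/Parent/Name attributes and correct
#' CDS phase; byte-stable for fixed input.
#'
#' @param transcripts List of [transcript()] objects (one gene per
#'   transcript).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(transcripts, path) {
  rows <- character(0L)
  for (tr in transcripts) {
    ex <- tr$cds_exons
    span <- c(min(ex$start), max(ex$end))
    gid <- paste0("gene:", tr$gene)
    rows <- c(rows,
      sprintf("%s\trdebscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              tr$chrom, span[1L], span[2L], tr$strand, gid, tr$gene),
      sprintf("%s\trdebscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              tr$chrom, span[1L], span[2L], tr$strand, tr$id, gid))
    # phase = bases to discard before the first complete codon of the exon,
    # accumulated in translation order (descending coordinates on "-")
    tord <- if (tr$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    before <- 0L
    phase <- integer(nrow(ex))
    for (k in tord) {
      phase[k] <- (3L - before %% 3L) %% 3L
      before <- before + (ex$end[k] - ex$start[k] + 1L)
    }
    rows <- c(rows, sprintf(
      "%s\trdebscreen\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
      tr$chrom, ex$start, ex$end, tr$strand, phase, tr$id, tr$id))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
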
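#' Read a VCF file into a site set
#'
#' Supports the VCF v4.2 subset this pipeline consumes: `##` meta lines, a
#' `#CHROM` header row, tab-separated records with GT as the first FORMAT
#' key. Only CHROM/POS/REF/ALT and the per-sample GT are semantic;
#' QUAL/FILTER/INFO are ignored. Multi-allelic records are decomposed with
#' [split_multiallelic()] on read, so the returned site count can exceed the
#' record count. Records are returned in file order.
#'
#' @param path Path to a plain-text VCF file.
#' @return A [site_set()]; its `samples` follow the header column order.
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) {
    stop("VCF format error in ", path, ": expected exactly one #CHROM header row",
         call. = FALSE)
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 10L || hdr[9L] != "FORMAT") {
    stop("VCF format error in ", path,
         ": need FORMAT and at least one sample column", call. = FALSE)
  }
  samples <- hdr[-(1:9)]
  if (anyDuplicated(samples)) {
    stop("VCF format error in ", path, ": duplicate sample names", call. = FALSE)
  }

  rec_lines <- which(seq_along(lines) > hdr_idx & nzchar(lines))
  if (length(rec_lines) == 0L) {
    return(site_set(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(character(), 0L, length(samples),
             dimnames = list(NULL, samples))
    ))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fmt <- v@gt[, "FORMAT"]
  not_gt <- which(sub(":.*$", "", fmt) != "GT")
  if (length(not_gt) > 0L) {
    stop("VCF format error at line ", rec_lines[not_gt[1L]], " of ", path,
         ": GT must be the first FORMAT key", call. = FALSE)
  }

  pieces <- lapply(seq_len(nrow(v@fix)), function(i) {
    gts <- v@gt[i, samples]
    names(gts) <- samples
    split_multiallelic(
      chrom = v@fix[i, "CHROM"],
      pos   = as.integer(v@fix[i, "POS"]),
      ref   = v@fix[i, "REF"],
      alts  = strsplit(v@fix[i, "ALT"], ",", fixed = TRUE)[[1L]],
      gts   = gts
    )
  })
  sites <- unlist(pieces, recursive = FALSE)
  variants <- data.frame(
    chrom = vapply(sites, function(s) s$variant$chrom, character(1L)),
    pos   = vapply(sites, function(s) s$variant$pos, integer(1L)),
    ref   = vapply(sites, function(s) s$variant$ref, character(1L)),
    alt   = vapply(sites, function(s) s$variant$alt, character(1L))
  )
  geno <- do.call(rbind, lapply(sites, function(s) s$genotypes[samples]))
  colnames(geno) <- samples
  site_set(variants, geno)
}

state_to_gt <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")

#' Write a site set as a minimal GT-only VCF
#'
#' Emits a VCF v4.2 header and one biallelic record per site, sorted by
#' (chrom, pos); ID/QUAL/FILTER/INFO are written as ".". Output is
#' byte-stable for fixed input, and [read_vcf()] inverts it exactly.
#'
#' @param ss A [site_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ss, path) {
  stopifnot(inherits(ss, "site_set"))
  ord <- order(ss$variants$chrom, ss$variants$pos, ss$variants$alt)
  v <- ss$variants[ord, , drop = FALSE]
  g <- ss$genotypes[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ss$samples), collapse = "\t")
  )
  recs <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".", ".",
            "GT", state_to_gt[g[i, ]]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, recs), path)
  invisible(path)
}
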
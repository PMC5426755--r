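#' Genotype states used throughout the pipeline
#'
#' Genotypes are reduced to four unphased diploid states; phase information
#' is discarded on parse because no downstream analysis uses it.
#'
#' @format Character vector of the four state labels.
#' @export
GT_STATES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

# Parse a diploid GT token into its two allele indices.
# Returns an integer vector of length 2; NA elements mark missing alleles.
gt_alleles <- function(gt) {
  if (length(gt) != 1L || is.na(gt)) return(c(NA_integer_, NA_integer_))
  core <- sub(":.*$", "", gt)
  parts <- strsplit(core, "[/|]", perl = TRUE)[[1L]]
  if (!all(grepl("^(\\.|[0-9]+)$", parts)) || core == "") {
    stop("malformed GT token '", core, "'", call. = FALSE)
  }
  if (length(parts) != 2L) {
    stop("unsupported ploidy in GT token '", core,
         "': only diploid genotypes are supported", call. = FALSE)
  }
  suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
}

#' Parse a VCF GT field into a genotype state
#'
#' Accepts diploid, biallelic GT tokens ("0/0", "0/1", "1/1", "./.") with
#' either "/" or "|" separators; phased and unphased forms map to the same
#' state. Any allele index greater than 1 is an error: multi-allelic records
#' must be decomposed with [split_multiallelic()] first.
#'
#' @param gt A single GT token (trailing FORMAT subfields after ":" are
#'   ignored). `NA` is treated as missing.
#' @return One of `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`.
#' @examples
#' parse_genotype("1/1") # "HOM_ALT"
#' parse_genotype("0|1") # "HET"
#' parse_genotype("./.") # "MISSING"
#' @export
parse_genotype <- function(gt) {
  al <- gt_alleles(gt)
  if (anyNA(al)) return("MISSING")
  if (any(al > 1L)) {
    stop("allele index > 1 in GT token '", gt,
         "': split multi-allelic records first", call. = FALSE)
  }
  c("HOM_REF", "HET", "HOM_ALT")[sum(al) + 1L]
}

# Genotype state of one sample with respect to alt allele j of a k-alt record.
# Alleles other than j (including ref) count as non-target, so "2/2" against
# alt 1 is HOM_REF-equivalent: the recessive filter only asks about the
# target allele's dosage. Any missing allele gives MISSING.
genotype_vs_alt <- function(gt, j, n_alt) {
  al <- gt_alleles(gt)
  if (anyNA(al)) return("MISSING")
  if (any(al > n_alt)) {
    stop("allele index ", max(al), " exceeds ALT count ", n_alt,
         " in GT token '", gt, "'", call. = FALSE)
  }
  c("HOM_REF", "HET", "HOM_ALT")[sum(al == j) + 1L]
}

#' Construct a variant
#'
#' A normalized biallelic substitution or indel with 1-based, fully closed
#' genomic coordinates (matching VCF POS).
#'
#' @param chrom Chromosome name (exact string; no "chr" normalization is
#'   ever applied).
#' @param pos 1-based genomic position of the first REF base.
#' @param ref,alt Non-empty uppercase DNA allele strings; must differ.
#' @return A list of class `"variant"`.
#' @export
variant <- function(chrom, pos, ref, alt) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer", call. = FALSE)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop("ref and alt must be non-empty uppercase DNA strings", call. = FALSE)
  }
  if (ref == alt) stop("ref and alt alleles must differ", call. = FALSE)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt),
            class = "variant")
}

#' Is a variant a single-base substitution?
#' @param v A [variant()].
#' @return Logical.
#' @export
is_substitution <- function(v) nchar(v$ref) == 1L && nchar(v$alt) == 1L

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s\n", x$chrom, x$pos, x$ref, x$alt))
  invisible(x)
}

#' Construct a set of genotyped sites
#'
#' The central container for a multi-sample call set: a variant table plus a
#' site-by-sample matrix of genotype states.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per biallelic site).
#' @param genotypes Character matrix of [GT_STATES], `nrow(variants)` rows,
#'   one named column per sample.
#' @return A list of class `"site_set"` with elements `variants`,
#'   `genotypes` and `samples`.
#' @export
site_set <- function(variants, genotypes) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  genotypes <- as.matrix(genotypes)
  if (nrow(variants) > 0L) {
    storage.mode(genotypes) <- "character"
    if (nrow(genotypes) != nrow(variants)) {
      stop("genotype matrix rows must match variant rows", call. = FALSE)
    }
    bad <- !(genotypes %in% GT_STATES)
    if (any(bad)) stop("unknown genotype state: ", genotypes[bad][1L], call. = FALSE)
  }
  samples <- colnames(genotypes)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("genotype matrix needs unique sample column names", call. = FALSE)
  }
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  rownames(genotypes) <- NULL
  structure(list(variants = variants, genotypes = genotypes, samples = samples),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> %d sites x %d samples (%s)\n",
              nrow(x$variants), length(x$samples),
              paste(utils::head(x$samples, 4L), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a site set
#' @param ss A [site_set()].
#' @return Integer count of sites.
#' @export
n_sites <- function(ss) nrow(ss$variants)

# Row-subset a site_set, preserving sample columns.
subset_sites <- function(ss, keep) {
  site_set(ss$variants[keep, , drop = FALSE],
           ss$genotypes[keep, , drop = FALSE])
}

#' Split a multi-allelic VCF record into biallelic sites
#'
#' One output site per ALT allele, in ALT order. Per-sample genotypes are
#' recoded relative to the target allele: alleles other than the target
#' (reference or another alt) count as non-target, so a "1/2" genotype is
#' HET for both output sites and "2/2" is HOM_ALT for the second site only.
#' A biallelic record passes through content-unchanged.
#'
#' @param chrom,pos,ref Record coordinates and reference allele.
#' @param alts Character vector of ALT alleles (length >= 1).
#' @param gts Named character vector of raw GT tokens, one per sample.
#' @return List of length `length(alts)`; each element has `variant` (a
#'   [variant()]) and `genotypes` (named character vector of states).
#' @export
split_multiallelic <- function(chrom, pos, ref, alts, gts) {
  if (length(alts) < 1L) stop("record has no ALT allele", call. = FALSE)
  stopifnot(!is.null(names(gts)))
  k <- length(alts)
  lapply(seq_len(k), function(j) {
    states <- vapply(gts, genotype_vs_alt, character(1L), j = j, n_alt = k)
    list(variant = variant(chrom, pos, ref, alts[[j]]), genotypes = states)
  })
}
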
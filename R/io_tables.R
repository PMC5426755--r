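#' Read a pedigree from a 6-column PED file
#'
#' Whitespace-separated columns: family, individual id, sire, dam, sex,
#' phenotype. `0` parents are recorded as unknown (`NA`); sex codes 1 = male,
#' 2 = female, anything else unknown; phenotype codes 2 = affected,
#' 1 = unaffected, 0 or -9 unknown.
#'
#' @param path PED file path.
#' @return A `data.frame` of class `"pedigree"` with columns `family`, `id`,
#'   `sire`, `dam`, `sex`, `phenotype`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) != 6L) {
    stop("PED file must have exactly 6 columns: ", path, call. = FALSE)
  }
  names(tab) <- c("family", "id", "sire", "dam", "sex", "phenotype")
  pedigree(data.frame(
    family = tab$family,
    id = tab$id,
    sire = ifelse(tab$sire == "0", NA_character_, tab$sire),
    dam = ifelse(tab$dam == "0", NA_character_, tab$dam),
    sex = unname(c("1" = "male", "2" = "female")[tab$sex]),
    phenotype = unname(c("2" = "affected", "1" = "unaffected")[tab$phenotype]),
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate a pedigree
#'
#' @param df `data.frame` with columns `id`, `sire`, `dam`, `sex`,
#'   `phenotype` (and optionally `family`); `NA` for unknown parents, sex
#'   and phenotype.
#' @return `df` with class `"pedigree"` prepended.
#' @export
pedigree <- function(df) {
  stopifnot(all(c("id", "sire", "dam", "sex", "phenotype") %in% names(df)))
  if (is.null(df$family)) df$family <- "FAM1"
  df$sex[!(df$sex %in% c("male", "female"))] <- "unknown"
  df$phenotype[!(df$phenotype %in% c("affected", "unaffected"))] <- "unknown"
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id in pedigree: ",
         df$id[duplicated(df$id)][1L], call. = FALSE)
  }
  si <- match(df$sire, df$id)
  di <- match(df$dam, df$id)
  bad <- (!is.na(df$sire) & is.na(si)) | (!is.na(df$dam) & is.na(di))
  if (any(bad)) {
    p <- c(df$sire[bad], df$dam[bad])
    p <- p[!is.na(p) & !(p %in% df$id)]
    stop("pedigree parent '", p[1L], "' is not an individual in the pedigree",
         call. = FALSE)
  }
  # acyclicity: generation-by-generation peel; anything never reached sits
  # on a parentage cycle
  settled <- logical(nrow(df))
  repeat {
    reach <- !settled &
      (is.na(si) | settled[pmax(si, 1L)] | is.na(df$sire)) &
      (is.na(di) | settled[pmax(di, 1L)] | is.na(df$dam))
    if (!any(reach)) break
    settled <- settled | reach
  }
  if (!all(settled)) {
    stop("cyclic parentage involving: ",
         paste(df$id[!settled], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df[, c("family", "id", "sire", "dam", "sex", "phenotype")]
}

#' Write a pedigree as a 6-column PED file
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phe <- c(affected = "2", unaffected = "1", unknown = "0")[ped$phenotype]
  lines <- paste(ped$family, ped$id,
                 ifelse(is.na(ped$sire), "0", ped$sire),
                 ifelse(is.na(ped$dam), "0", ped$dam),
                 sex, phe, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene panel from a plain-text symbol list
#'
#' One symbol per line; `#` comments and blank lines are ignored; duplicates
#' collapse; case is preserved. An effectively empty panel is an error — a
#' panel that silently matches nothing is almost certainly a user mistake.
#'
#' @param path Panel file path.
#' @return Character vector of unique gene symbols.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  symbols <- unique(lines[nzchar(lines)])
  if (length(symbols) == 0L) {
    stop("gene panel is empty after removing comments/blank lines: ", path,
         call. = FALSE)
  }
  symbols
}

#' Read per-cohort genotype counts from TSV
#'
#' Expects the exact header `label`, `n_total`, `n_het`, `n_hom_alt`.
#'
#' @param path TSV file path.
#' @return A validated [cohort_counts()] `data.frame`.
#' @export
read_cohorts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("label", "n_total", "n_het", "n_hom_alt")
  if (!identical(names(tab), need)) {
    stop("cohort table header must be exactly: ",
         paste(need, collapse = "\t"), call. = FALSE)
  }
  cohort_counts(tab$label, tab$n_total, tab$n_het, tab$n_hom_alt)
}

#' Write per-cohort genotype counts as TSV
#' @param cohorts A [cohort_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  utils::write.table(cohorts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
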
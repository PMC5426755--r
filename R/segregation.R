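#' Check complete segregation under a fully penetrant recessive model
#'
#' Tests a candidate variant's genotypes against a pedigree under autosomal
#' recessive inheritance with full penetrance. Violation rules:
#' \describe{
#'   \item{affected_not_hom_alt}{an affected individual is not homozygous
#'     for the alternate allele}
#'   \item{unaffected_hom_alt}{an unaffected individual is homozygous — a
#'     violation, not a reduced-penetrance observation; a tolerant mode is
#'     deliberately not provided}
#'   \item{obligate_carrier_hom_ref}{a parent of an affected individual is
#'     homozygous reference}
#'   \item{mendelian_impossible}{offspring HOM_ALT with a HOM_REF parent,
#'     or offspring HOM_REF with a HOM_ALT parent}
#' }
#' Individuals without a genotype (or with MISSING) are skipped by the
#' genotype rules; unknown-phenotype individuals contribute to Mendelian
#' checks but not to phenotype rules.
#'
#' @param ped A [pedigree()].
#' @param genotypes Named character vector of [GT_STATES]; every name must
#'   be an individual in the pedigree.
#' @return A list of class `"segregation_report"`: `segregates` (logical),
#'   `violations` (`data.frame` of `id`, `rule`), `counts` (3x3 table of
#'   genotype state by phenotype over genotyped individuals), `penetrance`
#'   (fraction of known-phenotype homozygotes that are affected; `NA` if
#'   none).
#' @export
check_recessive_segregation <- function(ped, genotypes) {
  stopifnot(inherits(ped, "pedigree"))
  unknown <- setdiff(names(genotypes), ped$id)
  if (length(unknown) > 0L) {
    stop("genotype given for id(s) not in the pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gt_of <- function(id) {
    g <- if (id %in% names(genotypes)) genotypes[[id]] else "MISSING"
    if (g == "MISSING") NA_character_ else g
  }

  violations <- data.frame(id = character(), rule = character())
  add <- function(id, rule) {
    violations <<- rbind(violations, data.frame(id = id, rule = rule))
  }

  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    g <- gt_of(id)
    phe <- ped$phenotype[i]
    if (!is.na(g)) {
      if (phe == "affected" && g != "HOM_ALT") add(id, "affected_not_hom_alt")
      if (phe == "unaffected" && g == "HOM_ALT") add(id, "unaffected_hom_alt")
      for (p in c(ped$sire[i], ped$dam[i])) {
        if (is.na(p)) next
        pg <- gt_of(p)
        if (is.na(pg)) next
        if ((g == "HOM_ALT" && pg == "HOM_REF") ||
            (g == "HOM_REF" && pg == "HOM_ALT")) {
          add(id, "mendelian_impossible")
        }
      }
    }
    if (phe == "affected") {
      for (p in c(ped$sire[i], ped$dam[i])) {
        if (!is.na(p) && !is.na(gt_of(p)) && gt_of(p) == "HOM_REF") {
          add(p, "obligate_carrier_hom_ref")
        }
      }
    }
  }
  violations <- unique(violations)
  rownames(violations) <- NULL

  gts <- vapply(ped$id, gt_of, character(1L))
  typed <- !is.na(gts)
  counts <- table(
    factor(gts[typed], levels = c("HOM_REF", "HET", "HOM_ALT")),
    factor(ped$phenotype[typed],
           levels = c("affected", "unaffected", "unknown")),
    dnn = c("genotype", "phenotype")
  )
  hom_known <- counts["HOM_ALT", "affected"] + counts["HOM_ALT", "unaffected"]
  penetrance <- if (hom_known > 0L) {
    counts["HOM_ALT", "affected"] / hom_known
  } else {
    NA_real_
  }

  structure(list(segregates = nrow(violations) == 0L,
                 violations = violations,
                 counts = counts,
                 penetrance = penetrance),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("segregates: %s\n", if (x$segregates) "true" else "false"))
  print(x$counts)
  if (!is.na(x$penetrance)) {
    cat(sprintf("penetrance among homozygotes: %.3f\n", x$penetrance))
  }
  if (nrow(x$violations) > 0L) {
    cat("violations:\n")
    print(x$violations)
  }
  invisible(x)
}

#' Mendelian offspring genotype distribution
#'
#' Gamete-union probabilities for a biallelic locus given two parental
#' genotypes; symmetric in its arguments and always sums to 1.
#'
#' @param sire_genotype,dam_genotype Parental states (`"HOM_REF"`, `"HET"`
#'   or `"HOM_ALT"`; `"MISSING"` is an error).
#' @return Named numeric vector of probabilities over `HOM_REF`, `HET`,
#'   `HOM_ALT`.
#' @examples
#' expected_offspring_distribution("HET", "HET") # 0.25, 0.5, 0.25
#' @export
expected_offspring_distribution <- function(sire_genotype, dam_genotype) {
  p_alt <- c(HOM_REF = 0, HET = 0.5, HOM_ALT = 1)
  for (g in c(sire_genotype, dam_genotype)) {
    if (!(g %in% names(p_alt))) {
      stop("parental genotype must be observed (not '", g, "')",
           call. = FALSE)
    }
  }
  ps <- p_alt[[sire_genotype]]
  pd <- p_alt[[dam_genotype]]
  c(HOM_REF = (1 - ps) * (1 - pd),
    HET = ps * (1 - pd) + (1 - ps) * pd,
    HOM_ALT = ps * pd)
}

#' Write a segregation report to TSV
#'
#' One row per pedigree-relevant quantity plus the violation list; a
#' human-readable summary goes to the console via the print method.
#'
#' @param report A `"segregation_report"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segregation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("segregates\t%s",
                     if (report$segregates) "true" else "false"), con)
  writeLines(sprintf("penetrance\t%s",
                     ifelse(is.na(report$penetrance), "NA",
                            format(report$penetrance))), con)
  cn <- report$counts
  for (g in rownames(cn)) {
    for (p in colnames(cn)) {
      writeLines(sprintf("count_%s_%s\t%d", g, p, cn[g, p]), con)
    }
  }
  if (nrow(report$violations) > 0L) {
    writeLines(sprintf("violation\t%s:%s", report$violations$id,
                       report$violations$rule), con)
  }
  invisible(path)
}
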
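#' Configuration for the recessive filter funnel
#'
#' @param case_sample Sample id of the affected genome.
#' @param control_samples Character vector of control sample ids (must not
#'   include the case).
#' @param control_policy `"exclude_if_any_control_hom_alt"` (default) drops
#'   a site only when a control is homozygous for the same alternate allele
#'   — under a recessive model unaffected controls may legitimately be
#'   carriers. `"exclude_if_any_control_has_alt"` additionally drops sites
#'   with heterozygous controls, appropriate when controls are unrelated
#'   breeds unlikely to carry the allele.
#' @param coding_scope `"any_cds_overlap"` (default) keeps every variant
#'   that touches a CDS, synonymous included;
#'   `"protein_altering_only"` restricts to missense/nonsense/stop_lost/
#'   start_lost/coding_other.
#' @param panel Optional character vector of gene symbols; `NULL` skips the
#'   panel stage.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(case_sample,
                          control_samples = character(),
                          control_policy = c("exclude_if_any_control_hom_alt",
                                             "exclude_if_any_control_has_alt"),
                          coding_scope = c("any_cds_overlap",
                                           "protein_altering_only"),
                          panel = NULL) {
  control_policy <- match.arg(control_policy)
  coding_scope <- match.arg(coding_scope)
  stopifnot(is.character(case_sample), length(case_sample) == 1L)
  if (case_sample %in% control_samples) {
    stop("case sample '", case_sample, "' cannot also be a control",
         call. = FALSE)
  }
  structure(list(case_sample = case_sample,
                 control_samples = control_samples,
                 control_policy = control_policy,
                 coding_scope = coding_scope,
                 panel = panel),
            class = "filter_config")
}

check_sample <- function(ss, sample, role) {
  if (!(sample %in% ss$samples)) {
    stop(role, " sample '", sample, "' not genotyped; available samples: ",
         paste(ss$samples, collapse = ", "), call. = FALSE)
  }
}

#' Funnel stage: case homozygosity
#'
#' Keeps sites where the case genome is homozygous for the alternate
#' allele. HET and MISSING are excluded — the recessive model requires an
#' observed homozygous genotype, so an ungenotyped site cannot support a
#' candidate.
#'
#' @param ss A [site_set()].
#' @param case_sample Case sample id.
#' @return The surviving [site_set()].
#' @export
stage_case_homozygous <- function(ss, case_sample) {
  check_sample(ss, case_sample, "case")
  subset_sites(ss, ss$genotypes[, case_sample] == "HOM_ALT")
}

#' Funnel stage: control exclusion under the recessive model
#'
#' Under the default policy a site is removed iff at least one control is
#' homozygous for the same alternate allele; under the strict policy any
#' alternate allele in a control removes it. MISSING control genotypes
#' never exclude (absence of evidence).
#'
#' @param ss A [site_set()].
#' @param control_samples Control sample ids.
#' @param policy Control policy; see [filter_config()].
#' @return The surviving [site_set()].
#' @export
stage_control_exclusion <- function(ss, control_samples,
                                    policy = "exclude_if_any_control_hom_alt") {
  stopifnot(length(control_samples) >= 1L)
  for (s in control_samples) check_sample(ss, s, "control")
  g <- ss$genotypes[, control_samples, drop = FALSE]
  excl <- if (policy == "exclude_if_any_control_hom_alt") {
    rowSums(g == "HOM_ALT") > 0L
  } else if (policy == "exclude_if_any_control_has_alt") {
    rowSums(g == "HOM_ALT" | g == "HET") > 0L
  } else {
    stop("unknown control policy: ", policy, call. = FALSE)
  }
  subset_sites(ss, !excl)
}

#' Funnel stage: coding consequence
#'
#' Annotates every surviving site and keeps those overlapping a CDS
#' (optionally restricted to protein-altering consequences).
#'
#' @param ss A [site_set()].
#' @param transcripts List of [transcript()] objects.
#' @param genome Named character vector from [read_genome()].
#' @param scope Coding scope; see [filter_config()].
#' @return List with `ss` (surviving [site_set()]) and `annotations` (list
#'   of per-site annotation tables, aligned with the surviving rows).
#' @export
stage_coding <- function(ss, transcripts, genome,
                         scope = "any_cds_overlap") {
  altering <- c("missense", "nonsense", "stop_lost", "start_lost",
                "coding_other")
  anns <- lapply(seq_len(n_sites(ss)), function(i) {
    vv <- ss$variants[i, ]
    annotate_variant(variant(vv$chrom, vv$pos, vv$ref, vv$alt),
                     transcripts, genome)
  })
  keep <- vapply(anns, function(a) {
    if (nrow(a) == 0L) return(FALSE)
    if (scope == "any_cds_overlap") return(TRUE)
    best_annotation(a)$effect %in% altering
  }, logical(1L))
  list(ss = subset_sites(ss, keep), annotations = anns[keep])
}

#' Funnel stage: known-gene-panel intersection
#'
#' @param coding List from [stage_coding()].
#' @param panel Character vector of gene symbols (exact string match
#'   against the most severe annotation's gene).
#' @return List with the surviving `ss` and `annotations`.
#' @export
stage_panel <- function(coding, panel) {
  stopifnot(length(panel) >= 1L)
  keep <- vapply(coding$annotations, function(a) {
    best_annotation(a)$gene %in% panel
  }, logical(1L))
  list(ss = subset_sites(coding$ss, keep),
       annotations = coding$annotations[keep])
}

#' Run the staged recessive-model filter funnel
#'
#' Stages run in the fixed order: total, case-homozygous, control
#' exclusion, coding consequence, gene panel. Stages without the inputs to
#' run (no controls, no panel) are recorded as skipped and pass all sites
#' through. Survivor counts are recorded after each stage; counts are taken
#' after multi-allelic splitting, so "total" can exceed the raw VCF record
#' count.
#'
#' @param ss A [site_set()] (typically from [read_vcf()]).
#' @param config A [filter_config()].
#' @param transcripts List of [transcript()] objects.
#' @param genome Named character vector from [read_genome()].
#' @return A list of class `"funnel_report"`: `stages` (`data.frame` of
#'   stage, count, note) and `candidates` (`data.frame` with the surviving
#'   variants, gene, consequence class and HGVS strings).
#' @export
run_funnel <- function(ss, config, transcripts, genome) {
  stopifnot(inherits(config, "filter_config"))
  stages <- data.frame(stage = "total", count = n_sites(ss), note = "")

  cur <- stage_case_homozygous(ss, config$case_sample)
  stages <- rbind(stages, data.frame(stage = "case_homozygous",
                                     count = n_sites(cur), note = ""))

  if (length(config$control_samples) > 0L) {
    cur <- stage_control_exclusion(cur, config$control_samples,
                                   config$control_policy)
    stages <- rbind(stages, data.frame(stage = "control_exclusion",
                                       count = n_sites(cur), note = ""))
  } else {
    stages <- rbind(stages, data.frame(stage = "control_exclusion",
                                       count = n_sites(cur),
                                       note = "skipped"))
  }

  coding <- stage_coding(cur, transcripts, genome, config$coding_scope)
  stages <- rbind(stages, data.frame(stage = "coding",
                                     count = n_sites(coding$ss), note = ""))

  if (!is.null(config$panel)) {
    coding <- stage_panel(coding, config$panel)
    stages <- rbind(stages, data.frame(stage = "panel",
                                       count = n_sites(coding$ss), note = ""))
  } else {
    stages <- rbind(stages, data.frame(stage = "panel",
                                       count = n_sites(coding$ss),
                                       note = "skipped"))
  }

  cand <- coding$ss$variants
  if (nrow(cand) > 0L) {
    best <- do.call(rbind, lapply(coding$annotations, best_annotation))
    cand <- cbind(cand, best[, c("gene", "transcript_id", "effect",
                                 "hgvs_c", "hgvs_p")])
  } else {
    cand <- cbind(cand, data.frame(gene = character(),
                                   transcript_id = character(),
                                   effect = character(),
                                   hgvs_c = character(),
                                   hgvs_p = character()))
  }
  rownames(cand) <- NULL
  structure(list(stages = stages, candidates = cand),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Recessive-model filter funnel\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %6d %s\n", x$stages$stage[i], x$stages$count[i],
                x$stages$note[i]))
  }
  cat(sprintf("%d candidate variant(s)\n", nrow(x$candidates)))
  if (nrow(x$candidates) > 0L) {
    print(x$candidates)
  }
  invisible(x)
}

#' Write a funnel report to TSV files
#'
#' @param report A `"funnel_report"` from [run_funnel()].
#' @param stages_path,candidates_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_funnel_report <- function(report, stages_path, candidates_path) {
  utils::write.table(report$stages, stages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$candidates, candidates_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(stages_path, candidates_path))
}
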
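#' Construct a per-cohort genotype count table
#'
#' One row per screened cohort (typically a breed) with the counts from a
#' genotyping assay of a single variant.
#'
#' @param label Cohort labels (unique).
#' @param n_total Individuals genotyped.
#' @param n_het Heterozygous carriers.
#' @param n_hom_alt Homozygous alternate individuals.
#' @return `data.frame` of class `"cohort_counts"`.
#' @export
cohort_counts <- function(label, n_total, n_het, n_hom_alt = 0L) {
  df <- data.frame(label = as.character(label),
                   n_total = as.integer(n_total),
                   n_het = as.integer(n_het),
                   n_hom_alt = as.integer(n_hom_alt))
  if (anyDuplicated(df$label)) {
    stop("duplicate cohort labels", call. = FALSE)
  }
  if (any(df$n_total < 0L | df$n_het < 0L | df$n_hom_alt < 0L) ||
      any(df$n_het + df$n_hom_alt > df$n_total)) {
    stop("invalid cohort counts: need 0 <= n_het + n_hom_alt <= n_total",
         call. = FALSE)
  }
  class(df) <- c("cohort_counts", "data.frame")
  df
}

#' Carrier frequency of a cohort
#'
#' "Carrier" means heterozygote only: affected homozygotes are tallied
#' separately, so 13 carriers among 47 genotyped dogs give 13/47 = 27.7%
#' even when two of the 47 are homozygous affected.
#'
#' @param counts A [cohort_counts()] table (vectorized over rows).
#' @return Numeric vector `n_het / n_total`.
#' @export
carrier_frequency <- function(counts) {
  if (any(counts$n_total == 0L)) {
    stop("carrier frequency undefined for n_total = 0", call. = FALSE)
  }
  counts$n_het / counts$n_total
}

#' Alternate-allele frequency of a cohort
#'
#' @param counts A [cohort_counts()] table (vectorized over rows).
#' @return Numeric vector `(n_het + 2 n_hom_alt) / (2 n_total)`.
#' @export
allele_frequency <- function(counts) {
  if (any(counts$n_total == 0L)) {
    stop("allele frequency undefined for n_total = 0", call. = FALSE)
  }
  (counts$n_het + 2 * counts$n_hom_alt) / (2 * counts$n_total)
}

#' Render a proportion as a percent string
#'
#' One decimal place, rounding half away from zero (so 13/47 prints as
#' "27.7%").
#'
#' @param p Proportion(s) in `[0, 1]` (any real works).
#' @return Character vector like `"27.7%"`.
#' @export
format_percent <- function(p) {
  x <- p * 100
  r <- sign(x) * floor(abs(x) * 10 + 0.5) / 10
  paste0(formatC(r, format = "f", digits = 1), "%")
}

#' Wilson score confidence interval for a proportion
#'
#' Chosen over the Wald interval because it behaves at the boundaries: the
#' lower limit is exactly 0 at 0 successes and the upper limit exactly 1 at
#' n successes — precisely the situation of screening cohorts where the
#' allele is absent.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param confidence Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`, clipped to `[0, 1]`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0L || successes < 0L || successes > n) {
    stop("need 0 <= successes <= n with n > 0", call. = FALSE)
  }
  # the chi-squared small-count warning concerns the test, not the interval
  ci <- suppressWarnings(
    stats::prop.test(successes, n, conf.level = confidence,
                     correct = FALSE)$conf.int
  )
  c(lower = max(0, ci[1L]), upper = min(1, ci[2L]))
}

#' Multi-cohort screening summary
#'
#' Per-cohort carrier and allele frequencies with 95% Wilson intervals and
#' Hardy-Weinberg expected homozygote frequency, plus a breed-specificity
#' verdict: the variant is called breed-specific iff every non-index cohort
#' carries no alternate allele at all.
#'
#' @param cohorts A [cohort_counts()] table.
#' @param index_label Label of the index (discovery) cohort.
#' @return A list of class `"cohort_summary"`: `table` (per-cohort
#'   statistics), `index_label`, `non_index_total` (summed `n_total` over
#'   non-index cohorts) and `breed_specific` (logical verdict).
#' @export
screen_summary <- function(cohorts, index_label) {
  stopifnot(inherits(cohorts, "cohort_counts"))
  if (!(index_label %in% cohorts$label)) {
    stop("index cohort '", index_label, "' not in the table", call. = FALSE)
  }
  cf <- carrier_frequency(cohorts)
  af <- allele_frequency(cohorts)
  ci <- t(vapply(seq_len(nrow(cohorts)), function(i) {
    wilson_interval(cohorts$n_het[i], cohorts$n_total[i])
  }, numeric(2L)))
  tab <- data.frame(
    label = cohorts$label,
    n_total = cohorts$n_total,
    n_het = cohorts$n_het,
    n_hom_alt = cohorts$n_hom_alt,
    carrier_frequency = cf,
    carrier_pct = format_percent(cf),
    carrier_ci_lower = ci[, 1L],
    carrier_ci_upper = ci[, 2L],
    allele_frequency = af,
    hwe_expected_hom_alt = af^2
  )
  non_index <- cohorts$label != index_label
  structure(list(
    table = tab,
    index_label = index_label,
    non_index_total = sum(cohorts$n_total[non_index]),
    breed_specific = all(cohorts$n_het[non_index] == 0L &
                           cohorts$n_hom_alt[non_index] == 0L)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort screen (index: %s)\n", x$index_label))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("non-index individuals screened: %d\n", x$non_index_total))
  cat(sprintf("verdict: %s\n",
              if (x$breed_specific) "breed-specific" else "not breed-specific"))
  invisible(x)
}

#' Write a cohort screening summary to TSV
#'
#' Per-cohort rows followed by `#`-prefixed verdict lines.
#'
#' @param summary A `"cohort_summary"` from [screen_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(summary$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# non_index_total\t%d", summary$non_index_total), con)
  writeLines(sprintf("# verdict\t%s",
                     if (summary$breed_specific) "breed-specific"
                     else "not breed-specific"), con)
  invisible(path)
}
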
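test_that("the generator is byte-identical for a fixed config", {
  cfg <- small_sim_config(seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1)
  emit_dataset(small_sim_config(seed = 5L), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  emit_dataset(small_sim_config(seed = 6L), d3)
  expect_false(identical(readLines(file.path(d1, "study.vcf")),
                         readLines(file.path(d3, "study.vcf"))))
})

test_that("simulated CDSs are translation-clean with the causal CGA planted", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- small_sim_config(seed)
    gg <- build_genome_and_genes(cfg)
    for (tr in gg$transcripts) {
      prot <- oracle_protein(oracle_spliced_cds(tr, gg$genome))
      expect_identical(substring(prot, 1L, 1L), "M")
      expect_identical(substring(prot, nchar(prot), nchar(prot)), "*")
      expect_false(grepl("\\*", substring(prot, 1L, nchar(prot) - 1L)))
    }
    causal_tr <- gg$transcripts[[cfg$causal_gene_index]]
    expect_identical(
      reference_codon(causal_tr, cfg$causal_codon_number, gg$genome), "CGA")
  }
})

test_that("changing litter size does not perturb the genome stream", {
  a <- build_genome_and_genes(small_sim_config(9L))
  b <- build_genome_and_genes(small_sim_config(9L, litter_size = 12L))
  expect_identical(a$genome, b$genome)
})

test_that("the planted variant annotates as the truth record says", {
  cfg <- small_sim_config(4L)
  out <- withr::local_tempdir()
  d <- emit_dataset(cfg, out)
  # truth strings come from the construction (codon k, CGA->TGA), the
  # annotation from independent coordinate arithmetic on the emitted files
  g <- read_genome(d$paths$genome)
  trs <- read_gene_models(d$paths$gff3)
  ann <- annotate_variant(d$causal, trs, g)
  ann <- ann[ann$gene == "COL7A1", ]
  truth <- stats::setNames(d$truth$value, d$truth$key)
  expect_identical(ann$hgvs_c, unname(truth["hgvs_c"]))
  expect_identical(ann$hgvs_p, unname(truth["hgvs_p"]))
  expect_identical(ann$effect, "nonsense")
  expect_identical(ann$alt_codon, "TGA")
})

test_that("a minus-strand causal gene plants G>A genomically but C>T in CDS", {
  cfg <- small_sim_config(8L, causal_strand = "-")
  gg <- build_genome_and_genes(cfg)
  tr <- gg$transcripts[[cfg$causal_gene_index]]
  v <- plant_causal_variant(gg$genome, tr, cfg$causal_codon_number)
  expect_identical(v$ref, "G")
  expect_identical(v$alt, "A")
  ann <- annotate_variant(v, list(tr), gg$genome)
  expect_identical(ann$effect, "nonsense")
  expect_identical(ann$hgvs_c,
                   sprintf("c.%dC>T", 3L * (cfg$causal_codon_number - 1L) + 1L))
})

test_that("planting demands a CGA reference codon", {
  cfg <- small_sim_config(4L)
  gg <- build_genome_and_genes(cfg)
  tr <- gg$transcripts[[cfg$causal_gene_index]]
  expect_error(plant_causal_variant(gg$genome, tr, 2L), "not CGA")
})

test_that("litter simulation conserves counts and always segregates", {
  for (seed in 1:5) {
    cfg <- small_sim_config(seed)
    fam <- simulate_pedigree_genotypes(cfg)
    expect_identical(nrow(fam$pedigree), cfg$litter_size + 2L)
    expect_identical(length(fam$genotypes), cfg$litter_size + 2L)
    expect_true(check_recessive_segregation(fam$pedigree,
                                            fam$genotypes)$segregates)
    aff <- fam$pedigree$phenotype == "affected"
    expect_identical(unname(fam$genotypes[fam$pedigree$id[aff]]),
                     rep("HOM_ALT", sum(aff)))
  }
})

test_that("HET x HET transmission recovers the 1:2:1 ratio at large n", {
  cfg <- small_sim_config(11L, litter_size = 10000L)
  fam <- simulate_pedigree_genotypes(cfg)
  pups <- fam$genotypes[grep("^PUP", names(fam$genotypes))]
  n <- length(pups)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(pups == "HOM_ALT") - 0.25), 3 * se)
  expect_lt(abs(mean(pups == "HOM_REF") - 0.25), 3 * se)
  se_het <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(pups == "HET") - 0.5), 3 * se_het)
})

test_that("controls never carry the causal allele by construction", {
  for (seed in 1:5) {
    cfg <- small_sim_config(seed)
    gg <- build_genome_and_genes(cfg)
    tr <- gg$transcripts[[cfg$causal_gene_index]]
    v <- plant_causal_variant(gg$genome, tr, cfg$causal_codon_number)
    ss <- simulate_background_and_controls(cfg, gg$genome, v)
    i <- which(ss$variants$pos == v$pos)
    expect_identical(unname(ss$genotypes[i, "CASE"]), "HOM_ALT")
    ctrl <- ss$genotypes[i, grep("^CTRL", ss$samples, value = TRUE)]
    expect_true(all(ctrl == "HOM_REF"))
  }
})

test_that("configured carrier controls exercise the two control policies", {
  cfg <- small_sim_config(3L, n_controls_het_at_causal = 4L)
  out <- withr::local_tempdir()
  d <- emit_dataset(cfg, out)
  controls <- grep("^CTRL", d$sites$samples, value = TRUE)
  g <- read_genome(d$paths$genome)
  trs <- read_gene_models(d$paths$gff3)
  lax <- run_funnel(d$sites,
                    filter_config("CASE", controls, panel = cfg$panel_genes),
                    trs, g)
  strict <- run_funnel(
    d$sites,
    filter_config("CASE", controls,
                  control_policy = "exclude_if_any_control_has_alt",
                  panel = cfg$panel_genes),
    trs, g)
  # carrier controls do not hide the variant under the recessive policy
  expect_true(any(lax$candidates$pos == d$causal$pos))
  expect_false(any(strict$candidates$pos == d$causal$pos))
})

test_that("more controls never increase expected post-control counts", {
  # Monte-Carlo trend: with shared background variation the count of
  # case-homozygous sites surviving control exclusion is non-increasing
  # in the number of controls, on average across seeds
  post_control <- function(n_controls, seed) {
    cfg <- small_sim_config(seed, n_controls = n_controls,
                            background_site_count = 80L)
    gg <- build_genome_and_genes(cfg)
    tr <- gg$transcripts[[cfg$causal_gene_index]]
    v <- plant_causal_variant(gg$genome, tr, cfg$causal_codon_number)
    ss <- simulate_background_and_controls(cfg, gg$genome, v)
    controls <- grep("^CTRL", ss$samples, value = TRUE)
    n_sites(stage_control_exclusion(
      stage_case_homozygous(ss, "CASE"), controls))
  }
  seeds <- 1:20
  means <- vapply(c(2L, 8L, 31L), function(k) {
    mean(vapply(seeds, function(s) post_control(k, s), numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(means) <= 0))
})

test_that("emitted files all parse back and agree with the in-memory objects", {
  cfg <- small_sim_config(12L)
  out <- withr::local_tempdir()
  d <- emit_dataset(cfg, out)
  expect_identical(read_genome(d$paths$genome), d$genome)
  ss <- read_vcf(d$paths$vcf)
  expect_identical(ss$variants, d$sites$variants)
  expect_identical(ss$genotypes, d$sites$genotypes)
  expect_identical(read_pedigree(d$paths$ped), d$pedigree)
  expect_identical(read_panel(d$paths$panel), cfg$panel_genes)
  expect_identical(read_cohorts(d$paths$cohorts), cfg$cohorts)
  trs <- read_gene_models(d$paths$gff3)
  expect_identical(length(trs), cfg$n_genes)
  for (i in seq_along(trs)) {
    expect_identical(trs[[i]]$cds_exons, d$transcripts[[i]]$cds_exons)
    expect_identical(trs[[i]]$strand, d$transcripts[[i]]$strand)
  }
})

test_that("the default cohort table gives a breed-specific verdict", {
  s <- screen_summary(study_cohorts(), "Central Asian Shepherd Dog")
  expect_true(s$breed_specific)
  expect_identical(s$non_index_total, 143L)
})

test_that("background genotypes look Hardy-Weinberg in aggregate", {
  # smoke property at reduced scale: pooled chi-square over sites should
  # not be wildly off; loose threshold, this is not a calibrated test
  cfg <- small_sim_config(21L, n_controls = 63L,
                          background_site_count = 60L,
                          background_alt_freq_range = c(0.2, 0.4))
  gg <- build_genome_and_genes(cfg)
  tr <- gg$transcripts[[cfg$causal_gene_index]]
  v <- plant_causal_variant(gg$genome, tr, cfg$causal_codon_number)
  ss <- simulate_background_and_controls(cfg, gg$genome, v)
  bg <- ss$variants$pos != v$pos
  stats <- vapply(which(bg), function(i) {
    g <- ss$genotypes[i, ]
    n <- length(g)
    p <- (2 * sum(g == "HOM_ALT") + sum(g == "HET")) / (2 * n)
    exp_counts <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(sum(g == "HOM_REF"), sum(g == "HET"), sum(g == "HOM_ALT"))
    if (any(exp_counts < 1e-9)) return(NA_real_)
    sum((obs - exp_counts)^2 / exp_counts)
  }, numeric(1L))
  stats <- stats[is.finite(stats)]
  # under HWE each statistic is ~ chi-square(1 df-ish); the mean over many
  # sites should sit near 1, certainly below 3
  expect_lt(mean(stats), 3)
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(causal_codon_number = 1L), "interior")
  expect_error(sim_config(causal_codon_number = 1600L), "interior")
  expect_error(
    build_genome_and_genes(small_sim_config(1L, chrom_length = 1500L)),
    "layout error")
  expect_error(sim_config(n_controls_het_at_causal = 99L))
})
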
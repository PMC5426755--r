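test_that("genomic positions map to spliced CDS coordinates per strand", {
  tr <- transcript("t", "G", "chr1", "+",
                   data.frame(start = c(101L, 201L), end = c(160L, 260L)))
  expect_identical(cds_position(tr, 101L), 1L)
  # independent enumeration: walk all 120 CDS bases and index genomic 201
  all_pos <- c(101:160, 201:260)
  expect_identical(cds_position(tr, 201L), match(201L, all_pos)) # 61
  expect_identical(cds_position(tr, 201L), 61L)
  expect_true(is.na(cds_position(tr, 180L)))  # intronic
  expect_true(is.na(cds_position(tr, 50L)))   # upstream

  trm <- transcript("t", "G", "chr1", "-",
                    data.frame(start = 101L, end = 160L))
  expect_identical(cds_position(trm, 160L), 1L)
  expect_identical(cds_position(trm, 101L), 60L)
})

test_that("codon arithmetic links c. and p. numbering", {
  expect_identical(codon_index(1L),
                   data.frame(codon_number = 1L, codon_offset = 1L))
  expect_identical(codon_index(4579L),
                   data.frame(codon_number = 1527L, codon_offset = 1L))
  expect_identical(codon_index(6L),
                   data.frame(codon_number = 2L, codon_offset = 3L))
  # identity 3*(codon-1) + offset = c_pos over a range
  ci <- codon_index(1:300)
  expect_identical(3L * (ci$codon_number - 1L) + ci$codon_offset, 1:300)
  expect_error(codon_index(0L), ">= 1")
})

test_that("reference codons read off the genome in translation order", {
  tp <- toy_plus()
  expect_identical(reference_codon(tp$tr, 1L, tp$genome), "ATG")
  expect_identical(reference_codon(tp$tr, 2L, tp$genome), "CGA")
  expect_identical(reference_codon(tp$tr, 3L, tp$genome), "TAA")
  expect_error(reference_codon(tp$tr, 4L, tp$genome), "outside")

  tm <- toy_minus()
  expect_identical(reference_codon(tm$tr, 2L, tm$genome), "CGA")
  # oracle: reverse-complement the genomic CDS, then chunk into triplets
  expect_identical(oracle_codons(oracle_spliced_cds(tm$tr, tm$genome)),
                   c("ATG", "CGA", "TAA"))
})

test_that("codons translate under the standard genetic code", {
  expect_identical(translate_codon("CGA"), "R")
  expect_identical(translate_codon("TGA"), "*")
  expect_identical(translate_codon("ATG"), "M")
  expect_error(translate_codon("NGA"), "triplet")
  expect_error(translate_codon("AT"), "triplet")
})

test_that("substitution classes follow the recessive-screen severity rules", {
  expect_identical(classify_substitution("R", "*", 1527L, 2944L), "nonsense")
  expect_identical(classify_substitution("G", "S", 1906L, 2944L), "missense")
  expect_identical(classify_substitution("K", "K", 10L, 100L), "synonymous")
  expect_identical(classify_substitution("*", "Q", 100L, 100L), "stop_lost")
  expect_identical(classify_substitution("M", "T", 1L, 100L), "start_lost")
  # an alt stop at the terminator codon is not premature
  expect_identical(classify_substitution("*", "*", 100L, 100L), "synonymous")
})

test_that("a CGA->TGA substitution annotates as the expected nonsense change", {
  tp <- toy_plus()
  ann <- annotate_variant(variant("chrT", 14L, "C", "T"), list(tp$tr),
                          tp$genome)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$c_pos, 4L)
  expect_identical(ann$ref_codon, "CGA")
  expect_identical(ann$alt_codon, "TGA")
  expect_identical(ann$effect, "nonsense")
  expect_identical(ann$hgvs_c, "c.4C>T")
  expect_identical(ann$hgvs_p, "p.R2*")
})

test_that("minus-strand annotation complements alleles onto the coding strand", {
  tm <- toy_minus()
  # codon 2 first base sits at genomic 16 on the minus strand (G on the
  # genomic strand); the G>A change is C>T in coding coordinates
  expect_identical(cds_position(tm$tr, 16L), 4L)
  ann <- annotate_variant(variant("chrT", 16L, "G", "A"), list(tm$tr),
                          tm$genome)
  expect_identical(ann$hgvs_c, "c.4C>T")
  expect_identical(ann$hgvs_p, "p.R2*")
  expect_identical(ann$effect, "nonsense")
})

test_that("annotation refuses a variant whose ref contradicts the genome", {
  tp <- toy_plus()
  expect_error(
    annotate_variant(variant("chrT", 14L, "G", "T"), list(tp$tr), tp$genome),
    "reference mismatch"
  )
})

test_that("variants outside every CDS annotate to nothing", {
  tp <- toy_plus()
  expect_identical(nrow(annotate_variant(variant("chrT", 3L, "A", "C"),
                                         list(tp$tr), tp$genome)), 0L)
})

test_that("CDS indels are coding_other and never get codon arithmetic", {
  tp <- toy_plus()
  ann <- annotate_variant(variant("chrT", 13L, "GC", "G"), list(tp$tr),
                          tp$genome)
  expect_identical(ann$effect, "coding_other")
  expect_true(is.na(ann$hgvs_c))
})

test_that("HGVS c. strings format and parse as exact inverses", {
  expect_identical(format_hgvs_c(4579L, "C", "T"), "c.4579C>T")
  expect_identical(parse_hgvs_c("c.4579C>T"),
                   list(c_pos = 4579L, ref_base = "C", alt_base = "T"))
  set.seed(3)
  for (i in 1:20) {
    p <- sample(1:99999, 1L)
    b <- sample(c("A", "C", "G", "T"), 2L)
    s <- format_hgvs_c(p, b[1L], b[2L])
    expect_identical(parse_hgvs_c(s),
                     list(c_pos = p, ref_base = b[1L], alt_base = b[2L]))
  }
  expect_error(parse_hgvs_c("c.4579C>"), "not a valid")
  expect_error(parse_hgvs_c("p.R1527*"), "not a valid")
})

test_that("annotation agrees with the splice-and-chunk oracle on random transcripts", {
  set.seed(101)
  for (i in 1:100) {
    rt <- random_transcript()
    cds <- oracle_spliced_cds(rt$tr, rt$genome)
    codons <- oracle_codons(cds)
    # pick a random CDS base and substitute it
    c_pos <- sample(nchar(cds), 1L)
    gmap <- if (rt$tr$strand == "+") {
      unlist(Map(seq, rt$tr$cds_exons$start, rt$tr$cds_exons$end))
    } else {
      rev(unlist(Map(seq, rt$tr$cds_exons$start, rt$tr$cds_exons$end)))
    }
    gpos <- gmap[c_pos]
    gref <- substring(rt$genome[[1L]], gpos, gpos)
    galt <- sample(setdiff(c("A", "C", "G", "T"), gref), 1L)
    ann <- annotate_variant(variant("chrR", gpos, gref, galt), list(rt$tr),
                            rt$genome)
    expect_identical(nrow(ann), 1L)
    expect_identical(ann$c_pos, c_pos)
    k <- (c_pos - 1L) %/% 3L + 1L
    expect_identical(ann$ref_codon, codons[k])
    expect_identical(ann$ref_aa,
                     unname(Biostrings::GENETIC_CODE[[codons[k]]]))
    # oracle alt protein: substitute in the spliced CDS and retranslate
    alt_cds <- cds
    alt_base <- if (rt$tr$strand == "-") chartr("ACGT", "TGCA", galt) else galt
    substring(alt_cds, c_pos, c_pos) <- alt_base
    expect_identical(ann$alt_aa,
                     unname(Biostrings::GENETIC_CODE[[oracle_codons(alt_cds)[k]]]))
    expect_identical(ann$hgvs_c,
                     sprintf("c.%d%s>%s", c_pos,
                             substring(cds, c_pos, c_pos), alt_base))
  }
})

test_that("annotation is symmetric under genome mirroring", {
  # annotating v on a + transcript must equal annotating the mirrored
  # variant on the reverse-complemented genome with a - transcript
  set.seed(55)
  for (i in 1:20) {
    rt <- random_transcript()
    if (rt$tr$strand == "-") next
    L <- nchar(rt$genome[[1L]])
    mirror_genome <- c(chrR = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rt$genome[[1L]]))))
    mirror_tr <- transcript(rt$tr$id, rt$tr$gene, "chrR", "-",
                            data.frame(start = L - rt$tr$cds_exons$end + 1L,
                                       end = L - rt$tr$cds_exons$start + 1L))
    gmap <- unlist(Map(seq, rt$tr$cds_exons$start, rt$tr$cds_exons$end))
    gpos <- sample(gmap, 1L)
    gref <- substring(rt$genome[[1L]], gpos, gpos)
    galt <- sample(setdiff(c("A", "C", "G", "T"), gref), 1L)
    a1 <- annotate_variant(variant("chrR", gpos, gref, galt),
                           list(rt$tr), rt$genome)
    a2 <- annotate_variant(
      variant("chrR", L - gpos + 1L,
              chartr("ACGT", "TGCA", gref), chartr("ACGT", "TGCA", galt)),
      list(mirror_tr), mirror_genome)
    expect_identical(a1[, c("c_pos", "codon_number", "codon_offset",
                            "ref_codon", "alt_codon", "ref_aa", "alt_aa",
                            "effect", "hgvs_c", "hgvs_p")],
                     a2[, c("c_pos", "codon_number", "codon_offset",
                            "ref_codon", "alt_codon", "ref_aa", "alt_aa",
                            "effect", "hgvs_c", "hgvs_p")])
  }
})
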
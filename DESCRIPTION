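Package: rdebscreen
Title: Recessive-Model Variant Discovery and Carrier Screening for a Canine
    Blistering Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering and screening a fully penetrant
    autosomal recessive disease variant from case/control genome sequencing,
    modelled on the mapping of recessive dystrophic epidermolysis bullosa in
    Central Asian Shepherd dogs. Implements a staged case/control filter
    funnel under the recessive model, strand-aware coding-consequence
    annotation with HGVS c./p. nomenclature, known-gene-panel intersection,
    pedigree segregation checking under full penetrance, and cohort
    carrier-frequency statistics with Wilson score intervals. Ships a
    deterministic synthetic-study generator (genome fragment, multi-exon gene
    models, planted CGA-to-TGA nonsense variant, Mendelian litter, control
    genomes, breed cohorts) with a truth record for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
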
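Package: regscreen
Title: Multi-Omics Screening of Candidate Regulator Genes in Fungal Mutant Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating candidate regulator genes from a
    wild-type/mutant strain comparison that combines genome, transcriptome
    and secretome evidence. Annotates variant consequences (synonymous,
    missense, stop-gain, frameshift) against a reference genome and gene
    models, flags variants in promoter and terminator windows, calls
    differential gene expression with an empirical (M, D) noise-dominance
    probability, analyses differential protein secretion, and intersects the
    evidence with a transcription-factor gene list through three candidate
    rules. Includes small downstream procedures (delta-delta-Ct relative
    expression, enzyme activity units, pooled t-tests, biomass conversion),
    neighbour-joining protein phylogenies with Poisson-corrected distances
    and bootstrap support, and a synthetic-data generator that plants known
    variants, expression effects and candidates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
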
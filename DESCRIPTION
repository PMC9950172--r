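Package: triosplice
Title: Trio Exome Filtering with RNA-Based Validation of Loss-of-Function Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated prioritization of de novo loss-of-function variants from
    trio exome data with transcriptome-level validation. Implements a five-rule
    trio variant filter cascade with de novo, homozygous-recessive and
    compound-heterozygous classification; HGVS-style frameshift and splice-site
    consequence prediction on transcript models, including normalization of
    equivalent deletions (VCF left-alignment and the HGVS 3' rule); split-read
    splice-junction extraction, per-donor acceptor usage ratios and
    novel-junction detection against a reference catalog; allele-specific
    expression and mosaicism quantification with exact binomial and Fisher
    tests of DNA-versus-RNA allelic imbalance; weight-matrix and first-order
    Markov splice-site strength models with reference-versus-alternate delta
    scores; and a seeded synthetic trio study generator so that every stage is
    testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
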
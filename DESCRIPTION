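Package: estrpipe
Title: Somatic Short Tandem Repeat Mutations and Expression STRs in Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic short tandem repeat (STR) mutations
    in colorectal tumours: exhaustive perfect-repeat panel annotation from
    reference sequence and gene models, patient-matched somatic STR mutation
    calling with allele-dropout filtering, characterization of STR mutability
    by microsatellite-instability status, unit size and allele length,
    discovery of expression STRs (eSTRs) by per-locus linear modelling of
    rank-normalised expression with a permuted-genotype control, validation of
    eSTRs by predicting the direction of expression change after somatic
    mutation, and a repeat-type-stratified label-permutation test for elevated
    eSTR mutability. Includes a synthetic-cohort generator with planted
    mutation and expression effects so the whole pipeline is testable without
    access to restricted tumour data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    withr,
    pROC,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
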
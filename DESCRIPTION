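Package: tumorfidelity
Title: Genetic Fidelity Assessment of Patient-Derived Tumor Models from Exome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether a patient-derived pre-clinical tumor model
    (cell culture or mouse xenograft) is genetically faithful to its primary
    tumor. Implements quality-filtered somatic variant calling from matched
    tumor-normal allele counts, base-quality mixture-model artifact removal,
    xenograft mouse-read deconvolution from dual-genome alignment summaries,
    permutation-FDR statistical comparison of primary versus model mutant
    allele frequencies, normal-DNA contamination estimation, exome-coverage
    copy-number calling with GC correction and concordance scoring, and a
    synthetic matched-cohort generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    yaml
Config/testthat/edition: 3
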
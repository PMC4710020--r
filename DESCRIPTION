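Package: apoetyper
Title: Allele-Specific TaqMan qPCR Genotyping of APOE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls APOE epsilon2/epsilon3/epsilon4 genotypes from three
    allele-specific TaqMan real-time PCR reactions read out as FAM/HEX
    threshold cycles. Computes per-reaction delta-Ct (FAM minus the ACTB
    internal-control HEX, with undetermined FAM set to the cycle ceiling),
    classifies each allele against a per-reaction delta-Ct cut-off,
    applies plate and sample QC gates, and combines the three calls into
    one of the six APOE genotypes. Also provides ROC/Youden re-calibration
    of the cut-offs from sequencing-labelled training data, cohort
    summaries with allele frequencies and exact multi-allele
    Hardy-Weinberg tests, caller-versus-sequencing concordance reports,
    an in-silico allele-specificity check of the assay oligos under a
    3'-clamp primer-extension model, and a synthetic qPCR cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
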
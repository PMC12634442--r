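Package: amlintegrate
Title: Integrated Whole-Genome and Transcriptome Evidence for Pediatric AML Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence-integration framework for molecular diagnosis of pediatric
    acute myeloid leukemia (AML) from combined whole-genome (WGS) and
    whole-transcriptome (WTS) sequencing. Implements reportability rules for
    small variants (WGS VAF threshold with WTS rescue), FLT3-ITD evidence
    combination, CNV scale classification, KMT2A partial tandem duplication
    calling, structural-variant mechanism classification (in-frame fusion
    versus enhancer hijacking), expression-based validation of enhancer-hijack
    candidates, allele-specific expression, a WHO-style molecular
    classification rule engine with phased reporting, cross-platform
    concordance statistics, an ISCN karyotype parser, and a seedable
    multi-platform synthetic cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
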
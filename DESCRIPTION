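Package: trkfusions
Title: Rule-Based Oncogenicity Classification and Cohort Analytics for NTRK Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies RNA-detected NTRK1/NTRK2/NTRK3 gene fusions as oncogenic,
    likely oncogenic, or of unknown significance from fusion orientation,
    kinase-domain retention, a curated fusion-partner knowledge base, and
    reading-frame preservation computed by exon phase arithmetic. Provides the
    downstream cohort analytics used to characterise fusion-positive tumours
    (per-tumour-type prevalence, fusion recurrence, co-occurring driver
    alterations, oncoprint-style matrices, and TMB/PD-L1/MSI immunotherapy
    biomarker comparisons), together with a synthetic tumour-cohort simulator
    that emits transcript models, fusion calls, and specimen metadata with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
VignetteBuilder: knitr
Config/testthat/edition: 3
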
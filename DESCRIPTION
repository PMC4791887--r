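Package: mirfluid
Title: Exploratory miRNA RT-qPCR Biomarker Analysis in CSF and Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for exploratory microRNA RT-qPCR panel profiling of
    paired cerebrospinal fluid (CSF) and blood cohorts, aimed at screening
    biomarker candidates that separate Alzheimer's disease from other dementias.
    Implements detection filtering against negative controls, spike-in quality
    control, NormFinder-style reference stability ranking, global-mean delta-Ct
    normalization to relative expression levels, exact Mann-Whitney differential
    tables with Benjamini-Hochberg correction, Fisher presence/absence marker
    screens with odds ratios and sensitivity/specificity, leave-one-out logistic
    classification, a two-miRNA ratio biomarker with Youden-optimal cutoff,
    cohort demographic comparisons, blood-brain-barrier (Qalb) flagging, and a
    synthetic two-fluid cohort generator with limit-of-detection censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
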
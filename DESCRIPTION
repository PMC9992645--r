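Package: trioscreen
Title: Trio De Novo Variant QC and Candidate-Gene Evidence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the candidate-gene evidence workflow used in
    trio-sequencing studies of neurodevelopmental disorders: hard-filter
    quality control of trio VCFs and de novo variant calling, integration
    of cohort de novo events with published events and recurrent-site
    detection, deleteriousness-score group comparisons (CADD rank tests,
    SIFT/PolyPhen exact tests), a developmental-brain co-expression
    percentile statistic over known disease gene sets, and
    prenatal/postnatal expression-trajectory regression. A synthetic-data
    module generates expression atlases with latent co-expression modules
    and prenatal ramps, variant cohorts with shifted score distributions,
    and truth-labelled trio VCFs spanning every QC threshold, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
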
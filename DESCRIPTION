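Package: pnetmarkers
Title: Spectral-Count Proteomics and Biomarker Prognosis for Pancreatic
    Neuroendocrine Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for paired tumor/para-tumor spectral-count
    proteomics and downstream biomarker statistics in pancreatic
    neuroendocrine tumors. Implements NSAF/ppm label-free quantification
    with paired differential-expression calling, western-blot densitometry
    ratios, immunohistochemistry positivity scoring, methylation-specific
    PCR call handling, small-sample exact tests (minimum-likelihood Fisher,
    exact Mann-Whitney, Pearson chi-square), Kaplan-Meier / log-rank / Cox
    proportional-hazards survival analysis for single and concurrent
    protein markers, and a synthetic-data generator that emulates the
    paired four-sample proteomic design and a 306-patient clinical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
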
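Package: toxmetab
Title: Untargeted Metabolomics Toxicity Profiling for Nanoparticle Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for untargeted LC-MS metabolomics toxicity
    profiling of treated cell cultures: quality-control filtering of feature
    tables (noise thresholds, blank-ratio filter, internal-standard gate,
    pooled-QC RSD filter), viable-cell-number normalization, per-timepoint
    empirical-Bayes moderated differential statistics with Benjamini-Hochberg
    correction, NIPALS principal component analysis with cross-validated Q2,
    cross-mode feature matching at ppm tolerance, identification-level
    annotation, closed-form companion-assay calculators (dissolution
    stoichiometry, glutathione redox ratio, efficiency-corrected qPCR), and a
    synthetic-data generator emulating a two-condition time-course study
    design for end-to-end testing.
License: MIT
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
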
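Package: p65trans
Title: Quantification of NF-kB p65 Nuclear Translocation and Its
    Association with Late Radiation-Induced Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify nuclear translocation of the NF-kB p65
    subunit in peripheral blood mononuclear cells (PBMCs) and relate it to
    late radiation-induced skin and subcutaneous fibrosis. Implements
    automated immunofluorescence image analysis (DAPI nuclear
    segmentation, eroded nuclear masks, cytoplasmic ring masks, per-cell
    nuclear:cytoplasmic median-intensity ratios), Western-blot
    densitometry normalization against a histone H3 loading control with
    fraction-purity checks and peak-time selection, and the cohort-level
    statistics (Wilcoxon rank-sum, covariate-adjusted linear models,
    contingency tests, subgroup tables). A synthetic-data module generates
    fluorescence fields with ground truth, densitometry time courses, and
    calibrated patient cohorts so the whole pipeline is testable end to
    end without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
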
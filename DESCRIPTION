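Package: cnrquant
Title: Automated Nuclear and Cytoplasmic IHC Quantification with
    Prognostic Cut-Point Discovery
Version: 0.1.0
Authors@R:
    person("Moira", "Lenehan", email = "mlenehan@posteo.net",
           role = c("aut", "cre"))
Description: Tools for quantitative immunohistochemistry on tissue
    microarray (TMA) core images and the downstream prognostic analysis.
    Separates hematoxylin and DAB staining by colour deconvolution,
    classifies tumour versus stroma, lymphocytes and background with a
    supervised per-pixel classifier, quantifies positive staining in the
    nuclear and cytoplasmic compartments, and combines percentage and
    intensity into autoscores, including the nuclear autoscore and the
    cytoplasmic-to-nuclear ratio (CNR). Prognostic thresholds on the
    continuous scores are discovered with log-rank splitting survival
    trees selected by 10-fold cross-validation, and the cohort-level
    statistics (chi-square association tables, Kaplan-Meier, log-rank,
    Cox regression, Spearman correlation) are provided alongside. A
    synthetic-data module generates stained core images with pixel-level
    ground truth and patient cohorts with known covariate structure and
    proportional-hazards survival so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    png,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
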
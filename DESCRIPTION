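Package: mrmquant
Title: Quantification and Characterization of Targeted SRM/MRM Proteomics Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and applying targeted selected/multiple
    reaction monitoring (SRM/MRM) proteomics assays with stable-isotope-labeled
    internal standards. Covers in-silico tryptic digestion and proteotypic
    peptide selection, light/heavy transition-ratio quantification with
    automated interference screening, assay figures of merit following CPTAC
    practice (lower limits of detection and quantification, response-curve
    linearity, intra-/inter-assay and total coefficients of variation),
    heavy-standard-based run normalization, weighted peptide-to-protein rollup,
    differential abundance testing with false-discovery-rate control,
    principal component analysis and Ward clustering of protein profiles, and
    ANOVA-ranked biomarker-panel classification under leave-one-out
    cross-validation. A synthetic-data module emulates calibration dilution
    series, multi-day replicate designs, and multi-class clinical cohorts with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    randomForest,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
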
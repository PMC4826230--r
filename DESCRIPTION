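Package: mirct
Title: Validation Analysis of Blood miRNA qRT-PCR Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a complete qRT-PCR biomarker
    validation analysis for blood-borne microRNA panels in non-small cell
    lung cancer and COPD: well-level Ct curation (linear-range and quality
    filtering, triplicate merging, NA accounting and imputation),
    endogenous-control evaluation (coefficient of variation on the Ct and
    linearized scales, NormFinder-style variance-component stability),
    delta-Ct normalization, per-marker differential statistics (Welch t,
    Wilcoxon rank-sum, one-way ANOVA, Benjamini-Hochberg adjustment,
    Mann-Whitney AUC), directional screening-versus-validation concordance
    scoring, and radial-basis-function support vector machine panel
    classification under repeated stratified cross-validation with a
    permutation null. A seeded generator of Fluidigm-style well-level
    datasets with known ground truth makes every stage testable end to end
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
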
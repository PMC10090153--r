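Package: rankpurity
Title: Tumor Purity Estimation from Rank-Transformed Bulk Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of malignant cells (tumor purity) in bulk
    tumor RNA samples from their gene expression profiles. Expression values
    are rank-percentile transformed per sample, making predictions invariant
    to measurement units and platform scale (TPM, FPKM, counts, microarray
    intensities). Training is weakly supervised: consensus pseudo-ground-truth
    purity labels are built from multiple genomics-based purity estimates via
    extreme-value flagging, iterative-PCA imputation, per-cohort quantile
    normalization and a sample-wise median. A two-step, purity-range-stratified
    and cancer-type-balanced lasso strategy selects a sparse gene feature set,
    on which an ordinary least-squares model is fit. Includes cancer-type
    specific and leave-one-cancer-type-out training modes, per-cohort
    evaluation (Pearson correlation, RMSE, Wilcoxon signed-rank comparisons),
    single-cell feature validation, and a synthetic cancer/stroma mixture
    generator that makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
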
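Package: sadewas
Title: Epigenome-Wide Differential Methylation, Variability and meQTL
    Analysis for Systemic Autoimmune Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for blood DNA-methylation case/control studies of
    systemic autoimmune diseases, centred on mixed connective tissue disease
    (MCTD). Implements per-CpG differential methylation scanning on beta
    values with covariate adjustment, differential variability testing
    (Brown-Forsythe Levene test on covariate residuals), replication logic,
    reference-based leukocyte deconvolution, treatment-adjusted and
    treatment-stratified effect calling, cis-meQTL mapping with FDR control,
    additive-model case/control genetic association, SNP-methylation-disease
    mediation-triangle intersection, cross-disease effect comparison, and
    ROC/AUC evaluation of methylation biomarker panels. Ships a synthetic
    cohort generator that emulates the statistical structure of such studies
    (interferon-signature hypomethylation, case variance inflation, cell
    mixture, batch and demographic effects, cis genetic control) together
    with a ground-truth ledger for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
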
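Package: methylSigR
Title: Diagnostic and Prognostic DNA Methylation Signatures from Beta-Value
    Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates tumor/normal diagnostic signatures and
    survival prognostic signatures from Illumina-450K-style DNA methylation
    beta-value matrices. The diagnostic arm ranks differentially methylated
    markers by balanced accuracy at their optimal beta-value threshold,
    sizes a cumulative signed beta-sum (class-score) panel by repeated
    subsampling, and classifies samples against a quartile-derived cutoff.
    The prognostic arm screens markers by a survival-time fold-change
    statistic, selects a panel with cross-validated LASSO-Cox regression,
    and evaluates the resulting risk score by median-split Kaplan-Meier
    analysis and time-dependent ROC with inverse-probability-of-censoring
    weighting. Includes a seeded synthetic-cohort generator (methylation,
    survival, expression) with planted effects for end-to-end validation,
    a risk-score/expression correlation arm, and a random-signature
    permutation null for gene-set association.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    survival,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: DNAMethylation, Classification, Survival, MethylationArray
RoxygenNote: 7.3.3
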
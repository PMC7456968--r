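#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MethylationExperiment: a beta-value matrix with probe and sample metadata
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"beta"` assay (markers x samples, values in \[0,1\] or `NA`),
#' a probe manifest in `rowData()` (`chrom`, `unique_mapping`) and sample
#' annotations in `colData()` (`group` in \{tumor, normal\}, optionally
#' `os_time` / `os_status` for tumor samples plus clinical covariates).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [MethylationExperiment()] for the constructor,
#'   [betaValues()], [probeManifest()], [sampleGroups()], [survivalOutcome()].
#' @exportClass MethylationExperiment
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (!is.numeric(b))
            msg <- c(msg, "assay 'beta' must be numeric")
        else {
            rng <- range(b, na.rm = TRUE)
            if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
                msg <- c(msg, "beta values must lie in [0, 1]")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate marker ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    cd <- SummarizedExperiment::colData(object)
    if ("group" %in% colnames(cd) &&
        !all(cd$group %in% c("tumor", "normal")))
        msg <- c(msg, "colData$group must be 'tumor' or 'normal'")
    if (length(msg)) msg else TRUE
})

#' Diagnostic class-score signature
#'
#' An ordered panel of methylation markers with per-marker direction
#' (hyper- or hypomethylated in tumor), the balanced accuracy and optimal
#' beta threshold found at ranking time, the panel size `k`, and the
#' class-score cutoff MT = Q1 - 1.5 (Q3 - Q1) of the training tumor
#' class-scores. Samples whose signed cumulative beta sum (class-score)
#' is greater than or equal to `cutoff` are called tumor.
#'
#' @slot markers data.frame with columns `marker_id`, `direction`
#'   (`"hyper"`/`"hypo"`), `ba`, `threshold`; rows in the balanced-accuracy
#'   ranking used at fit time.
#' @slot k integer panel size (the first `k` rows of `markers` are used).
#' @slot cutoff numeric class-score cutoff (MT).
#' @slot training list with the training group mean class-scores.
#' @exportClass DiagnosticSignature
setClass("DiagnosticSignature",
    representation(markers = "data.frame", k = "integer",
                   cutoff = "numeric", training = "list"))

setValidity("DiagnosticSignature", function(object) {
    msg <- character()
    need <- c("marker_id", "direction", "ba", "threshold")
    if (!all(need %in% colnames(object@markers)))
        msg <- c(msg, paste("markers must have columns",
                            paste(need, collapse = ", ")))
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "k must be a single integer >= 1")
    else if (object@k > nrow(object@markers))
        msg <- c(msg, "k exceeds the number of ranked markers")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
        msg <- c(msg, "cutoff must be a single finite number")
    if (!all(object@markers$direction %in% c("hyper", "hypo")))
        msg <- c(msg, "direction must be 'hyper' or 'hypo'")
    if (length(msg)) msg else TRUE
})

#' Prognostic risk-score model
#'
#' A multivariate Cox proportional-hazards model over a small panel of
#' methylation markers. The per-sample risk score is the linear predictor
#' sum(coef_m * beta_m); samples with risk score greater than or equal to
#' `riskCutoff` (the training median) are high-risk.
#'
#' @slot coefficients named numeric vector of log hazard ratios per unit
#'   beta, names are marker ids.
#' @slot lambda numeric; the cross-validated LASSO penalty at which the
#'   panel was selected (`NA` when LASSO was not used).
#' @slot riskCutoff numeric; training median risk score.
#' @exportClass PrognosticModel
setClass("PrognosticModel",
    representation(coefficients = "numeric", lambda = "numeric",
                   riskCutoff = "numeric"))

setValidity("PrognosticModel", function(object) {
    msg <- character()
    if (is.null(names(object@coefficients)) ||
        anyDuplicated(names(object@coefficients)))
        msg <- c(msg, "coefficients must be uniquely named by marker id")
    if (!all(is.finite(object@coefficients)))
        msg <- c(msg, "coefficients must be finite")
    if (length(object@riskCutoff) != 1L || !is.finite(object@riskCutoff))
        msg <- c(msg, "riskCutoff must be a single finite number")
    if (length(msg)) msg else TRUE
})
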
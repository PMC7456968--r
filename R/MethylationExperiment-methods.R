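#' Construct a MethylationExperiment
#'
#' Bundles a beta-value matrix with its probe manifest and sample
#' annotations into a single validated container.
#'
#' @param beta numeric matrix, markers x samples, values in \[0,1\] or `NA`;
#'   rownames are marker ids, colnames sample ids.
#' @param manifest data.frame with columns `marker_id`, `chrom`,
#'   `unique_mapping` (logical or 0/1) covering every row of `beta`, or
#'   `NULL` to record no manifest.
#' @param annotation data.frame with columns `sample_id`, `group`
#'   (`"tumor"`/`"normal"`) and optionally `os_time`, `os_status` and
#'   clinical covariates, or `NULL`.
#' @param metadata list of free-form metadata (e.g. simulation ground truth).
#'
#' @return a [MethylationExperiment-class] object.
#' @examples
#' b <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' me <- MethylationExperiment(b)
#' dim(me)
#' @export
MethylationExperiment <- function(beta, manifest = NULL, annotation = NULL,
                                  metadata = list()) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)))
        stop("beta must have marker ids as rownames")
    if (is.null(colnames(beta)))
        stop("beta must have sample ids as colnames")
    rd <- S4Vectors::DataFrame(row.names = rownames(beta))
    if (!is.null(manifest)) {
        manifest <- as.data.frame(manifest)
        miss <- setdiff(rownames(beta), manifest$marker_id)
        if (length(miss))
            stop("manifest does not cover marker(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        manifest <- manifest[match(rownames(beta), manifest$marker_id), ,
                             drop = FALSE]
        rd$chrom <- as.character(manifest$chrom)
        rd$unique_mapping <- as.logical(manifest$unique_mapping)
    }
    cd <- S4Vectors::DataFrame(row.names = colnames(beta))
    if (!is.null(annotation)) {
        annotation <- as.data.frame(annotation)
        miss <- setdiff(colnames(beta), annotation$sample_id)
        if (length(miss))
            stop("annotation does not cover sample(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        annotation <- annotation[match(colnames(beta),
                                       annotation$sample_id), , drop = FALSE]
        for (nm in setdiff(colnames(annotation), "sample_id"))
            cd[[nm]] <- annotation[[nm]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), rowData = rd, colData = cd,
        metadata = metadata)
    methods::new("MethylationExperiment", se)
}

#' Beta-value matrix of a MethylationExperiment
#' @param x a [MethylationExperiment-class].
#' @return numeric matrix, markers x samples.
#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationExperiment", function(x)
    SummarizedExperiment::assay(x, "beta"))

#' Probe manifest of a MethylationExperiment
#' @param x a [MethylationExperiment-class].
#' @return data.frame with `marker_id`, `chrom`, `unique_mapping`.
#' @rdname probeManifest
#' @export
setMethod("probeManifest", "MethylationExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    data.frame(marker_id = rownames(x),
               chrom = if ("chrom" %in% colnames(rd)) rd$chrom else NA,
               unique_mapping = if ("unique_mapping" %in% colnames(rd))
                   rd$unique_mapping else NA,
               stringsAsFactors = FALSE)
})

#' Tumor/normal group labels
#' @param x a [MethylationExperiment-class].
#' @return character vector named by sample id.
#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "MethylationExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"group" %in% colnames(cd))
        stop("no 'group' column in colData")
    stats::setNames(as.character(cd$group), colnames(x))
})

#' Survival outcomes of the tumor samples
#' @param x a [MethylationExperiment-class].
#' @return data.frame `sample_id`, `os_time`, `os_status`, restricted to
#'   samples with non-missing survival.
#' @rdname survivalOutcome
#' @export
setMethod("survivalOutcome", "MethylationExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("os_time", "os_status") %in% colnames(cd)))
        stop("no survival columns (os_time, os_status) in colData")
    keep <- !is.na(cd$os_time) & !is.na(cd$os_status)
    data.frame(sample_id = colnames(x)[keep],
               os_time = as.numeric(cd$os_time[keep]),
               os_status = as.integer(cd$os_status[keep]),
               stringsAsFactors = FALSE)
})

setMethod("show", "MethylationExperiment", function(object) {
    cat("MethylationExperiment with", nrow(object), "markers and",
        ncol(object), "samples\n")
    g <- tryCatch(sampleGroups(object), error = function(e) NULL)
    if (!is.null(g))
        cat("  groups:", sum(g == "tumor"), "tumor /",
            sum(g == "normal"), "normal\n")
    b <- betaValues(object)
    cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(b))))
    invisible(object)
})

#' @rdname signatureMarkers
#' @param x a [DiagnosticSignature-class].
#' @return data.frame of the `k` markers in panel order.
#' @export
setMethod("signatureMarkers", "DiagnosticSignature", function(x)
    utils::head(x@markers, x@k))

#' @rdname signatureCutoff
#' @param x a [DiagnosticSignature-class].
#' @return numeric class-score cutoff (MT).
#' @export
setMethod("signatureCutoff", "DiagnosticSignature", function(x) x@cutoff)

setMethod("show", "DiagnosticSignature", function(object) {
    m <- signatureMarkers(object)
    cat("DiagnosticSignature with", object@k, "markers",
        sprintf("(class-score cutoff %.4g)\n", object@cutoff))
    cat("  ", paste0(m$marker_id, " (", m$direction, ")", collapse = ", "),
        "\n", sep = "")
    invisible(object)
})

#' Model coefficients
#' @param object a [PrognosticModel-class].
#' @return named numeric vector of per-marker Cox coefficients.
#' @export
setMethod("coef", "PrognosticModel", function(object) object@coefficients)

setMethod("show", "PrognosticModel", function(object) {
    cat("PrognosticModel with", length(object@coefficients), "markers",
        sprintf("(risk cutoff %.4g", object@riskCutoff))
    if (is.finite(object@lambda))
        cat(sprintf(", lambda %.4g", object@lambda))
    cat(")\n")
    cf <- object@coefficients
    cat("  risk score =",
        paste(sprintf("%s%.4g x %s", ifelse(cf >= 0, "+", "-"),
                      abs(cf), names(cf)), collapse = " "), "\n")
    invisible(object)
})

# -- internal coercion helpers -------------------------------------------

# Accept a MethylationExperiment or a plain marker x sample matrix.
.beta_of <- function(x) {
    if (methods::is(x, "MethylationExperiment")) betaValues(x)
    else as.matrix(x)
}

# Group labels: from the object or an explicit vector aligned to columns.
.groups_of <- function(x, groups = NULL) {
    if (is.null(groups)) {
        if (!methods::is(x, "MethylationExperiment"))
            stop("supply 'groups' when x is a plain matrix")
        groups <- sampleGroups(x)
    }
    groups <- as.character(groups)
    if (!all(groups %in% c("tumor", "normal")))
        stop("groups must be 'tumor' or 'normal'")
    if (length(groups) != ncol(.beta_of(x)))
        stop("groups length does not match the number of samples")
    groups
}

# Survival data.frame aligned to the given sample ids.
.surv_align <- function(surv, sample_ids) {
    surv <- as.data.frame(surv)
    need <- c("sample_id", "os_time", "os_status")
    if (!all(need %in% colnames(surv)))
        stop("survival data must have columns ",
             paste(need, collapse = ", "))
    idx <- match(sample_ids, surv$sample_id)
    if (anyNA(idx))
        stop("no survival record for sample(s): ",
             paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
    out <- surv[idx, , drop = FALSE]
    if (any(out$os_time <= 0)) stop("os_time must be positive")
    if (!all(out$os_status %in% c(0, 1))) stop("os_status must be 0/1")
    out
}
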
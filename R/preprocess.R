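#' Probe-level quality filtering
#'
#' Two-step probe filtering: (1) markers on sex chromosomes or not mapping
#' uniquely to the genome are removed; (2) markers observed in fewer than
#' `availabilityMin` of samples are removed. The sample set is unchanged.
#' A filter report with the count removed per rule is attached.
#'
#' @param x a [MethylationExperiment-class], or a beta matrix (then supply
#'   `manifest`).
#' @param manifest data.frame `marker_id`, `chrom`, `unique_mapping`; taken
#'   from `rowData(x)` for a MethylationExperiment.
#' @param availabilityMin minimum non-missing fraction per marker, in
#'   (0, 1\]; default 0.9.
#'
#' @details Sex chromosomes are the labels X, Y, chrX, chrY
#'   (case-insensitive). Rules are applied in order; a marker is counted
#'   under the first rule that removes it. The operation is idempotent.
#'
#' @return the filtered object of the same class; the report is in
#'   `metadata(x)$filter_report` (or `attr(,"filter_report")` for a matrix)
#'   with fields `n_input`, `n_sex_chrom`, `n_multimap`, `n_low_availability`,
#'   `n_retained`.
#' @examples
#' me <- simulateMethylation(cohortConfig(n_tumor = 10, n_normal = 5,
#'                                        n_markers = 100, seed = 1))
#' filtered <- filterProbes(me)
#' S4Vectors::metadata(filtered)$filter_report
#' @rdname filterProbes
#' @export
setMethod("filterProbes", "MethylationExperiment",
    function(x, ..., availabilityMin = 0.9) {
        b <- betaValues(x)
        man <- probeManifest(x)
        res <- .filter_probes(b, man, availabilityMin)
        out <- x[res$keep, ]
        md <- S4Vectors::metadata(out)
        md$filter_report <- res$report
        if (!is.null(md$beta_complete))
            md$beta_complete <- md$beta_complete[res$keep, , drop = FALSE]
        S4Vectors::metadata(out) <- md
        out
    })

#' @rdname filterProbes
#' @export
setMethod("filterProbes", "matrix",
    function(x, manifest, ..., availabilityMin = 0.9) {
        res <- .filter_probes(x, manifest, availabilityMin)
        out <- x[res$keep, , drop = FALSE]
        attr(out, "filter_report") <- res$report
        out
    })

.SEX_CHROM <- c("x", "y", "chrx", "chry")

.filter_probes <- function(beta, manifest, availabilityMin) {
    if (!is.numeric(availabilityMin) || availabilityMin <= 0 ||
        availabilityMin > 1)
        stop("availabilityMin must be in (0, 1]")
    manifest <- as.data.frame(manifest)
    idx <- match(rownames(beta), manifest$marker_id)
    if (anyNA(idx))
        stop("marker(s) missing from the manifest: ",
             paste(utils::head(rownames(beta)[is.na(idx)], 5),
                   collapse = ", "))
    chrom <- tolower(as.character(manifest$chrom[idx]))
    uniq <- as.logical(manifest$unique_mapping[idx])
    sex <- chrom %in% .SEX_CHROM
    mm <- !sex & !uniq
    avail <- rowMeans(!is.na(beta))
    low <- !sex & !mm & avail < availabilityMin
    keep <- !(sex | mm | low)
    list(keep = keep,
         report = list(n_input = nrow(beta),
                       n_sex_chrom = sum(sex),
                       n_multimap = sum(mm),
                       n_low_availability = sum(low),
                       n_retained = sum(keep)))
}

#' Median imputation of missing beta values
#'
#' Each missing entry is replaced by the median beta value of the same
#' marker over the remaining samples. Observed entries are never altered.
#'
#' @param x a [MethylationExperiment-class] or beta matrix.
#' @return the same class with no missing values.
#' @examples
#' b <- matrix(c(0.2, 0.4, NA, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' imputeMissing(b)["cg1", "s3"]  # 0.3
#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "MethylationExperiment", function(x) {
    b <- .impute_missing(betaValues(x))
    SummarizedExperiment::assay(x, "beta") <- b
    x
})

#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "matrix", function(x) .impute_missing(x))

.impute_missing <- function(beta) {
    if (!anyNA(beta)) return(beta)
    all_na <- rowSums(!is.na(beta)) == 0
    if (any(all_na))
        stop("marker(s) with no observed values (filter first): ",
             paste(utils::head(rownames(beta)[all_na], 5), collapse = ", "))
    na_rows <- which(rowSums(is.na(beta)) > 0)
    for (i in na_rows) {
        miss <- is.na(beta[i, ])
        beta[i, miss] <- stats::median(beta[i, !miss])
    }
    beta
}

#' Between-sample quantile normalization
#'
#' Full quantile normalization across samples via
#' [limma::normalizeBetweenArrays] (default method for a single-channel
#' matrix): after normalization every sample's sorted beta vector equals
#' the row-wise mean of the sorted input vectors, so all samples share one
#' empirical distribution. Rank order within each sample is preserved;
#' tied input values receive the mean of the reference values at their
#' tied ranks.
#'
#' @param x a [MethylationExperiment-class] or beta matrix with no missing
#'   values (impute first).
#' @return the same class, normalized; values remain in \[0, 1\].
#' @rdname normalizeBetweenSamples
#' @export
setMethod("normalizeBetweenSamples", "MethylationExperiment", function(x) {
    b <- .normalize_quantiles(betaValues(x))
    SummarizedExperiment::assay(x, "beta") <- b
    x
})

#' @rdname normalizeBetweenSamples
#' @export
setMethod("normalizeBetweenSamples", "matrix",
    function(x) .normalize_quantiles(x))

.normalize_quantiles <- function(beta) {
    if (anyNA(beta))
        stop("missing values present: run imputeMissing() first")
    if (ncol(beta) < 2) return(beta)
    out <- limma::normalizeBetweenArrays(beta, method = "quantile")
    dimnames(out) <- dimnames(beta)
    out
}
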
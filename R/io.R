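# Delimited-text readers/writers for the pipeline's artifacts. Tab- and
# comma-delimited files are both accepted; empty fields and "NA" are
# missing.

.read_delim_auto <- function(path) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      na.strings = c("NA", ""), check.names = FALSE,
                      stringsAsFactors = FALSE)
}

.read_matrix <- function(path, what) {
    df <- .read_delim_auto(path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate ", what, " id(s) in ", path, ": ",
             paste(utils::head(ids[duplicated(ids)], 5), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample id(s) in ", path)
    if (!is.numeric(m)) {
        bad <- which(is.na(suppressWarnings(
            matrix(as.numeric(m), nrow(m)))) & !is.na(m),
            arr.ind = TRUE)[1, ]
        stop("non-numeric cell in ", path, " at row '", ids[bad[1]],
             "', column '", colnames(m)[bad[2]], "'")
    }
    rownames(m) <- ids
    m
}

#' Read a beta-value matrix
#'
#' Tab- or comma-delimited, first column marker ids, header of sample
#' ids. Empty fields and "NA" are missing; any value outside \[0,1\] is
#' rejected with its cell location.
#'
#' @param path file path.
#' @return numeric matrix, markers x samples.
#' @export
readBetaMatrix <- function(path) {
    m <- .read_matrix(path, "marker")
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop("beta value outside [0, 1] in ", path, " at row '",
             rownames(m)[bad[1, 1]], "', column '",
             colnames(m)[bad[1, 2]], "'")
    m
}

#' Write a beta-value matrix as TSV
#' @param beta matrix or [MethylationExperiment-class].
#' @param path output path.
#' @export
writeBetaMatrix <- function(beta, path) {
    m <- .beta_of(beta)
    df <- data.frame(marker_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an expression matrix (genes x samples)
#' @param path file path.
#' @return numeric matrix.
#' @export
readExpressionMatrix <- function(path) .read_matrix(path, "gene")

#' Write an expression matrix as TSV
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(expr, path) {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a probe manifest (marker_id, chrom, unique_mapping)
#' @param path file path.
#' @return data.frame.
#' @export
readProbeManifest <- function(path) {
    df <- .read_delim_auto(path)
    need <- c("marker_id", "chrom", "unique_mapping")
    if (!all(need %in% colnames(df)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    df$unique_mapping <- as.logical(as.numeric(df$unique_mapping) != 0 |
                                    df$unique_mapping %in% c(TRUE, "TRUE"))
    df
}

#' Write a probe manifest as TSV
#' @param manifest data.frame `marker_id`, `chrom`, `unique_mapping`.
#' @param path output path.
#' @export
writeProbeManifest <- function(manifest, path) {
    manifest$unique_mapping <- as.integer(manifest$unique_mapping)
    utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read sample annotations (sample_id, group, optional survival/covariates)
#' @param path file path.
#' @return data.frame.
#' @export
readSampleAnnotation <- function(path) {
    df <- .read_delim_auto(path)
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("annotation must have columns sample_id, group")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id(s) in ", path)
    if (!all(df$group %in% c("tumor", "normal")))
        stop("group must be 'tumor' or 'normal' in ", path)
    df
}

#' Write sample annotations as TSV
#' @param annotation data.frame.
#' @param path output path.
#' @export
writeSampleAnnotation <- function(annotation, path) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Serialize a diagnostic signature to JSON
#' @param sig a [DiagnosticSignature-class].
#' @param path output path.
#' @export
writeSignature <- function(sig, path) {
    jsonlite::write_json(
        list(markers = sig@markers, k = sig@k, cutoff = sig@cutoff,
             training = sig@training),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a diagnostic signature from JSON
#' @param path file path.
#' @return a [DiagnosticSignature-class].
#' @export
readSignature <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("DiagnosticSignature",
                 markers = as.data.frame(x$markers),
                 k = as.integer(x$k), cutoff = as.numeric(x$cutoff),
                 training = as.list(x$training))
}

#' Serialize a prognostic model to JSON
#' @param model a [PrognosticModel-class].
#' @param path output path.
#' @export
writePrognosticModel <- function(model, path) {
    jsonlite::write_json(
        list(markers = data.frame(id = names(model@coefficients),
                                  coef = unname(model@coefficients)),
             lambda = model@lambda, risk_cutoff = model@riskCutoff),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a prognostic model from JSON
#' @param path file path.
#' @return a [PrognosticModel-class].
#' @export
readPrognosticModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("PrognosticModel",
                 coefficients = stats::setNames(as.numeric(x$markers$coef),
                                                x$markers$id),
                 lambda = as.numeric(x$lambda),
                 riskCutoff = as.numeric(x$risk_cutoff))
}
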
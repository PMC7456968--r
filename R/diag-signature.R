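#' Balanced accuracy from a confusion table
#'
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2` — the mean of sensitivity and
#' specificity, robust to tumor/normal class imbalance.
#'
#' @param tp,fn,tn,fp confusion counts (tumor is the positive class).
#' @return balanced accuracy in \[0, 1\].
#' @examples
#' balancedAccuracy(8, 2, 9, 1)  # 0.85
#' @export
balancedAccuracy <- function(tp, fn, tn, fp) {
    if (tp + fn < 1) stop("empty positive class (tp + fn = 0)")
    if (tn + fp < 1) stop("empty negative class (tn + fp = 0)")
    (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Optimal single-marker beta threshold by balanced accuracy
#'
#' Scans every achievable decision rule for one marker: candidate
#' thresholds are the midpoints between consecutive distinct observed beta
#' values (plus one candidate below the smallest and above the largest
#' value, kept inside \[0,1\]), in both orientations (call tumor when
#' beta >= t, or when beta <= t). Returns the orientation/threshold pair
#' maximizing balanced accuracy; direction is `"hyper"` iff the
#' tumor-when-high orientation wins. Orientation ties prefer `"hyper"`;
#' threshold ties take the smallest threshold.
#'
#' @param beta_row numeric beta values for one marker.
#' @param groups `"tumor"`/`"normal"` per sample.
#' @return list `ba`, `threshold`, `direction`, `constant` (TRUE with a
#'   warning when the marker is constant; then `ba = 0.5`).
#' @export
optimalThreshold <- function(beta_row, groups) {
    groups <- as.character(groups)
    is_t <- groups == "tumor"
    if (!any(is_t) || !any(!is_t))
        stop("both groups must be non-empty")
    if (length(beta_row) != length(groups))
        stop("beta_row and groups lengths differ")
    v <- sort(unique(beta_row))
    if (length(v) == 1L) {
        warning("constant beta vector: balanced accuracy 0.5")
        return(list(ba = 0.5, threshold = v, direction = "hyper",
                    constant = TRUE))
    }
    nt <- sum(is_t); nn <- sum(!is_t)
    # per-distinct-value tumor/normal counts, cumulated left to right
    f <- factor(beta_row, levels = v)
    ct <- cumsum(tapply(is_t, f, sum, default = 0))
    cn <- cumsum(tapply(!is_t, f, sum, default = 0))
    # interior cut k (k = 1..K-1): threshold is the midpoint between
    # distinct values k and k+1. The boundary cuts (call everyone or no
    # one tumor) score exactly BA 0.5 in some orientation and the interior
    # maximum over both orientations is always >= 0.5, so they never win.
    K <- length(v)
    cum_t <- ct[-K]; cum_n <- cn[-K]
    # tumor-when-high at cut k: call tumor for values with index > k
    ba_high <- ((nt - cum_t) / nt + cum_n / nn) / 2
    ba_low <- 1 - ba_high
    thr <- (v[-K] + v[-1]) / 2
    bh <- max(ba_high); bl <- max(ba_low)
    if (bh >= bl)
        list(ba = bh, threshold = thr[which.max(ba_high)],
             direction = "hyper", constant = FALSE)
    else
        list(ba = bl, threshold = thr[which.max(ba_low)],
             direction = "hypo", constant = FALSE)
}

#' Rank candidate markers by balanced accuracy
#'
#' Descending balanced accuracy; ties broken by smaller FDR then
#' lexicographic marker id.
#'
#' @param candidates data.frame with `marker_id`, `ba`, and optionally
#'   `fdr` (plus any further columns, e.g. `direction`, `threshold`).
#' @return the same data.frame, re-ordered.
#' @export
rankMarkers <- function(candidates) {
    if (nrow(candidates) == 0) stop("no candidate markers to rank")
    fdr <- if ("fdr" %in% colnames(candidates)) candidates$fdr else
        rep(0, nrow(candidates))
    ord <- order(-candidates$ba, fdr, candidates$marker_id)
    out <- candidates[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rank diagnostic candidates on a cohort
#'
#' Convenience wrapper: runs [optimalThreshold()] for each candidate
#' marker, attaches direction fixed from the full-training Ave_T vs Ave_N
#' comparison (not from the winning orientation), and ranks with
#' [rankMarkers()].
#'
#' @param x a [MethylationExperiment-class] or beta matrix.
#' @param stats data.frame from [computeMarkerStats()] (supplies fdr and
#'   the global hyper/hypo direction).
#' @param marker_ids candidate markers (e.g. from
#'   [preselectDiagnosticCandidates()]).
#' @param groups group labels when `x` is a matrix.
#' @return ranked data.frame `marker_id`, `direction`, `ba`, `threshold`,
#'   `fdr`.
#' @export
rankDiagnosticCandidates <- function(x, stats, marker_ids, groups = NULL) {
    beta <- .beta_of(x)
    groups <- .groups_of(x, groups)
    missing <- setdiff(marker_ids, rownames(beta))
    if (length(missing))
        stop("marker(s) absent from the beta matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    st <- stats[match(marker_ids, stats$marker_id), , drop = FALSE]
    res <- lapply(marker_ids, function(m)
        optimalThreshold(beta[m, ], groups))
    cand <- data.frame(marker_id = marker_ids,
                       direction = st$direction,
                       ba = vapply(res, `[[`, numeric(1), "ba"),
                       threshold = vapply(res, `[[`, numeric(1),
                                          "threshold"),
                       fdr = st$fdr, stringsAsFactors = FALSE)
    rankMarkers(cand)
}

#' Cumulative signed class-scores
#'
#' The class-score of sample j over the top k ranked markers is the signed
#' cumulative beta sum: `+beta` for hypermethylated markers
#' (Ave_T > Ave_N), `-beta` for hypomethylated markers.
#'
#' @param x a [MethylationExperiment-class] or beta matrix.
#' @param markers data.frame with `marker_id` and `direction` in ranked
#'   order (e.g. from [rankDiagnosticCandidates()]).
#' @param k number of top markers to sum; default all.
#' @return numeric vector of class-scores named by sample id.
#' @export
classScores <- function(x, markers, k = nrow(markers)) {
    beta <- .beta_of(x)
    if (k < 1 || k > nrow(markers))
        stop("k must be in 1..", nrow(markers))
    m <- markers[seq_len(k), , drop = FALSE]
    missing <- setdiff(m$marker_id, rownames(beta))
    if (length(missing))
        stop("marker(s) absent from the beta matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    sgn <- ifelse(m$direction == "hyper", 1, -1)
    colSums(beta[m$marker_id, , drop = FALSE] * sgn)
}

#' Class-score cutoff MT from training tumor scores
#'
#' `MT = Q1 - 1.5 (Q3 - Q1)`, where Q1/Q3 are the lower/upper quartiles of
#' the tumor class-scores (linear interpolation between order statistics).
#' Samples with class-score not less than MT are called tumor.
#'
#' @param scores_tumor class-scores of the training tumor samples (>= 4).
#' @return the cutoff MT.
#' @examples
#' tumorCutoff(c(1, 2, 3, 4, 5))  # -1
#' @export
tumorCutoff <- function(scores_tumor) {
    if (length(scores_tumor) < 4)
        stop("need at least 4 tumor scores for quartiles")
    q <- .quartiles(scores_tumor)
    q[1] - 1.5 * (q[2] - q[1])
}

#' Select the signature size by repeated subsampling
#'
#' For each of `nSim` simulations, a subsample of tumors and normals is
#' drawn without replacement; for every panel size k <= `kMax` the
#' class-scores are computed on the subsample, the cutoff MT is derived
#' from the subsample's tumor scores, samples are classified, and the
#' balanced accuracy recorded. The selected size k* maximizes the mean BA
#' over simulations (ties to the smallest k, favouring parsimony).
#'
#' @param x a [MethylationExperiment-class] or beta matrix.
#' @param ranked ranked marker data.frame (`marker_id`, `direction`, ...).
#' @param nSim number of subsampling simulations; default 100.
#' @param subsample integer c(n_tumor, n_normal) drawn per simulation;
#'   default half of each group.
#' @param kMax largest panel size examined; default `min(50, nrow(ranked))`.
#' @param seed RNG seed.
#' @param groups group labels when `x` is a matrix.
#' @return list `k_star`, `mean_ba` (length-kMax curve), `ba` (kMax x nSim
#'   matrix).
#' @export
selectSignatureSize <- function(x, ranked, nSim = 100, subsample = NULL,
                                kMax = min(50, nrow(ranked)), seed = 1,
                                groups = NULL) {
    beta <- .beta_of(x)
    groups <- .groups_of(x, groups)
    if (kMax < 1 || kMax > nrow(ranked))
        stop("kMax must be in 1..", nrow(ranked))
    tum <- which(groups == "tumor")
    nor <- which(groups == "normal")
    if (is.null(subsample))
        subsample <- c(floor(length(tum) / 2), floor(length(nor) / 2))
    if (subsample[1] > length(tum) || subsample[2] > length(nor))
        stop("subsample sizes exceed group sizes")
    if (subsample[1] < 4)
        stop("need at least 4 subsampled tumors for the quartile cutoff")
    m <- ranked[seq_len(kMax), , drop = FALSE]
    sgn <- ifelse(m$direction == "hyper", 1, -1)
    sb <- beta[m$marker_id, , drop = FALSE] * sgn
    ba <- matrix(NA_real_, kMax, nSim)
    .with_seed(seed, {
        for (s in seq_len(nSim)) {
            st <- sample(tum, subsample[1])
            sn <- sample(nor, subsample[2])
            S <- sb[, c(st, sn), drop = FALSE]
            S <- if (kMax == 1) S else apply(S, 2, cumsum)
            if (kMax == 1) dim(S) <- c(1L, length(st) + length(sn))
            it <- seq_along(st)
            q <- apply(S[, it, drop = FALSE], 1, .quartiles)
            mt <- q[1, ] - 1.5 * (q[2, ] - q[1, ])
            sens <- rowMeans(S[, it, drop = FALSE] >= mt)
            spec <- rowMeans(S[, -it, drop = FALSE] < mt)
            ba[, s] <- (sens + spec) / 2
        }
    })
    curve <- rowMeans(ba)
    list(k_star = which.max(curve), mean_ba = curve, ba = ba)
}

#' Fit the diagnostic signature
#'
#' Takes the top `k` ranked markers and derives the class-score cutoff
#' MT from the training tumor scores. Requires the paper-stated
#' orientation assumption: mean tumor class-score above mean normal
#' class-score.
#'
#' @param x training [MethylationExperiment-class] or beta matrix.
#' @param ranked ranked marker data.frame.
#' @param k panel size (e.g. `k_star` from [selectSignatureSize()]).
#' @param groups group labels when `x` is a matrix.
#' @return a [DiagnosticSignature-class].
#' @export
fitDiagnostic <- function(x, ranked, k, groups = NULL) {
    beta <- .beta_of(x)
    groups <- .groups_of(x, groups)
    sc <- classScores(beta, ranked, k)
    mt_t <- mean(sc[groups == "tumor"])
    mt_n <- mean(sc[groups == "normal"])
    if (!(mt_t > mt_n))
        stop("mean tumor class-score is not above the normal mean: ",
             "check marker directions")
    cutoff <- tumorCutoff(sc[groups == "tumor"])
    methods::new("DiagnosticSignature",
                 markers = as.data.frame(ranked), k = as.integer(k),
                 cutoff = cutoff,
                 training = list(mean_score_tumor = mt_t,
                                 mean_score_normal = mt_n))
}

#' Classify samples with a diagnostic signature
#'
#' A sample is called `"tumor"` iff its class-score is greater than or
#' equal to the signature cutoff, `"normal"` otherwise.
#'
#' @param x a [MethylationExperiment-class] or beta matrix.
#' @param sig a [DiagnosticSignature-class].
#' @return character vector of labels named by sample id.
#' @export
classifySamples <- function(x, sig) {
    sc <- classScores(x, signatureMarkers(sig), sig@k)
    ifelse(sc >= sig@cutoff, "tumor", "normal")
}

#' Evaluate diagnostic predictions
#'
#' Sensitivity, specificity, balanced accuracy, and (when continuous
#' scores are supplied) the ROC AUC computed by the trapezoidal rule over
#' all score thresholds.
#'
#' @param predicted,truth `"tumor"`/`"normal"` labels, aligned.
#' @param scores optional continuous class-scores (higher = more
#'   tumor-like).
#' @return list `sensitivity`, `specificity`, `ba`, `auc` (`NA` with
#'   `auc_defined = FALSE` when truth has a single class or no scores),
#'   and the confusion counts.
#' @export
evaluateDiagnostic <- function(predicted, truth, scores = NULL) {
    if (length(predicted) != length(truth))
        stop("predicted and truth lengths differ")
    is_t <- truth == "tumor"
    tp <- sum(predicted == "tumor" & is_t)
    fn <- sum(predicted == "normal" & is_t)
    tn <- sum(predicted == "normal" & !is_t)
    fp <- sum(predicted == "tumor" & !is_t)
    sens <- if (any(is_t)) tp / (tp + fn) else NA_real_
    spec <- if (any(!is_t)) tn / (tn + fp) else NA_real_
    auc <- NA_real_
    auc_def <- FALSE
    if (!is.null(scores) && any(is_t) && any(!is_t)) {
        auc <- rocAUC(scores, is_t)
        auc_def <- TRUE
    }
    list(sensitivity = sens, specificity = spec,
         ba = if (is.na(sens) || is.na(spec)) NA_real_ else
             (sens + spec) / 2,
         auc = auc, auc_defined = auc_def,
         tp = tp, fn = fn, tn = tn, fp = fp)
}

#' ROC AUC by the trapezoidal rule
#'
#' Sweeps every score threshold from high to low, accumulating the
#' (FPR, TPR) curve, and integrates by trapezoids (ties contribute a
#' diagonal segment, i.e. 0.5 credit).
#'
#' @param scores continuous scores, higher = more positive.
#' @param positive logical, TRUE for the positive class.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, positive) {
    positive <- as.logical(positive)
    if (!any(positive) || all(positive))
        stop("AUC undefined: single-class truth")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- positive[ord]
    # merge tied scores into single curve steps
    grp <- cumsum(!duplicated(s))
    tp <- tapply(p, grp, sum)
    fp <- tapply(!p, grp, sum)
    tpr <- c(0, cumsum(tp)) / sum(positive)
    fpr <- c(0, cumsum(fp)) / sum(!positive)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
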
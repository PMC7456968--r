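#' Per-marker differential methylation statistics
#'
#' For each marker: tumor/normal mean beta (Ave_T, Ave_N), unbiased sample
#' SDs (SD_T, SD_N), the floored log2 fold change
#' `log2(max(Ave_T, 0.01) / max(Ave_N, 0.01))`, a two-sided Wilcoxon
#' rank-sum p-value comparing tumor vs normal beta, and the
#' Benjamini-Hochberg FDR across all markers. Direction is `"hyper"` when
#' Ave_T > Ave_N, `"hypo"` otherwise.
#'
#' @param x a [MethylationExperiment-class] or beta matrix (no missing
#'   values).
#' @param groups `"tumor"`/`"normal"` per sample; taken from `colData` for
#'   a MethylationExperiment.
#'
#' @details The rank-sum test uses the exact distribution when both groups
#'   have at most 20 samples and no ties occur, and the normal
#'   approximation with tie correction otherwise.
#'
#' @return data.frame with one row per marker: `marker_id`, `ave_t`,
#'   `ave_n`, `sd_t`, `sd_n`, `log2fc`, `p_value`, `fdr`, `direction`.
#' @examples
#' me <- simulateMethylation(cohortConfig(n_tumor = 15, n_normal = 10,
#'                                        n_markers = 50, missing_rate = 0,
#'                                        seed = 2))
#' stats <- computeMarkerStats(me)
#' head(stats)
#' @export
computeMarkerStats <- function(x, groups = NULL) {
    beta <- .beta_of(x)
    groups <- .groups_of(x, groups)
    if (anyNA(beta))
        stop("missing values present: impute before computing statistics")
    is_t <- groups == "tumor"
    if (sum(is_t) < 2 || sum(!is_t) < 2)
        stop("need at least 2 samples per group")
    bt <- beta[, is_t, drop = FALSE]
    bn <- beta[, !is_t, drop = FALSE]
    ave_t <- rowMeans(bt)
    ave_n <- rowMeans(bn)
    sd_t <- apply(bt, 1, stats::sd)
    sd_n <- apply(bn, 1, stats::sd)
    log2fc <- log2(pmax(ave_t, 0.01) / pmax(ave_n, 0.01))
    exact <- sum(is_t) <= 20 && sum(!is_t) <= 20
    p <- vapply(seq_len(nrow(beta)), function(i) {
        xs <- bt[i, ]; ys <- bn[i, ]
        ex <- exact && !anyDuplicated(c(xs, ys))
        suppressWarnings(stats::wilcox.test(xs, ys, exact = ex)$p.value)
    }, numeric(1))
    data.frame(marker_id = rownames(beta), ave_t = ave_t, ave_n = ave_n,
               sd_t = sd_t, sd_n = sd_n, log2fc = log2fc, p_value = p,
               fdr = stats::p.adjust(p, method = "BH"),
               direction = ifelse(ave_t > ave_n, "hyper", "hypo"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Preselect diagnostic candidate markers
#'
#' Retains markers satisfying all three gates (strict inequalities):
#' (1) Ave_T > `aveMin` or Ave_N > `aveMin`;
#' (2) |log2 fold change| > `lfcMin` and FDR < `fdrMax`;
#' (3) SD_T < `sdMax` and SD_N < `sdMax`.
#'
#' @param stats data.frame from [computeMarkerStats()].
#' @param aveMin,lfcMin,fdrMax,sdMax gate thresholds; defaults 0.3, 1,
#'   0.01, 0.2.
#' @return list with `marker_ids` (retained, input order) and `report`
#'   (counts failing each gate and the retained count).
#' @export
preselectDiagnosticCandidates <- function(stats, aveMin = 0.3, lfcMin = 1,
                                          fdrMax = 0.01, sdMax = 0.2) {
    g1 <- stats$ave_t > aveMin | stats$ave_n > aveMin
    g2 <- abs(stats$log2fc) > lfcMin & stats$fdr < fdrMax
    g3 <- stats$sd_t < sdMax & stats$sd_n < sdMax
    keep <- g1 & g2 & g3
    list(marker_ids = stats$marker_id[keep],
         report = list(n_input = nrow(stats),
                       n_fail_mean = sum(!g1),
                       n_fail_fc_fdr = sum(!g2),
                       n_fail_sd = sum(!g3),
                       n_retained = sum(keep)))
}
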
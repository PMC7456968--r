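#' Genome-wide Pearson correlation of a risk score with gene expression
#'
#' Per gene: Pearson r between expression and the risk score over shared
#' samples, with a two-sided p-value from the t-distribution transform
#' `t = r sqrt((n-2)/(1-r^2))`. Also reports the top-k significantly
#' positively and negatively correlated genes.
#'
#' @param scores numeric risk scores named by sample id.
#' @param expr genes x samples expression matrix.
#' @param topK size of the top lists; default 10.
#' @param pMax significance threshold for the top lists; default 0.001.
#' @return list `table` (data.frame `gene_id`, `r`, `p`), `top_positive`,
#'   `top_negative` (gene ids), `excluded` (zero-variance gene ids).
#' @export
correlateScoreWithGenes <- function(scores, expr, topK = 10,
                                    pMax = 0.001) {
    expr <- as.matrix(expr)
    if (!is.null(names(scores))) {
        shared <- intersect(names(scores), colnames(expr))
        if (length(shared) < 3)
            stop("need at least 3 shared samples")
        scores <- scores[shared]
        expr <- expr[, shared, drop = FALSE]
    } else if (length(scores) != ncol(expr))
        stop("scores length does not match the number of samples")
    n <- length(scores)
    if (n < 3) stop("need at least 3 shared samples")
    sds <- apply(expr, 1, stats::sd)
    excluded <- rownames(expr)[sds == 0]
    keep <- sds > 0
    r <- as.numeric(stats::cor(scores, t(expr[keep, , drop = FALSE])))
    p <- .pearson_p(r, n)
    tab <- data.frame(gene_id = rownames(expr)[keep], r = r, p = p,
                      stringsAsFactors = FALSE)
    sig <- tab[tab$p < pMax, , drop = FALSE]
    pos <- sig[sig$r > 0, , drop = FALSE]
    neg <- sig[sig$r < 0, , drop = FALSE]
    list(table = tab,
         top_positive = utils::head(pos$gene_id[order(-pos$r)], topK),
         top_negative = utils::head(neg$gene_id[order(neg$r)], topK),
         excluded = excluded)
}

# two-sided Pearson p via the t transform, df = n - 2
.pearson_p <- function(r, n) {
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Correlation of one methylation marker with one gene
#'
#' @param beta_row numeric beta values of one marker.
#' @param expr_row numeric expression of one gene, same samples.
#' @return list `r`, `p`, `n`.
#' @export
correlateMarkerWithGene <- function(beta_row, expr_row) {
    if (length(beta_row) != length(expr_row))
        stop("vectors differ in length")
    ok <- is.finite(beta_row) & is.finite(expr_row)
    n <- sum(ok)
    if (n < 3) stop("need at least 3 shared samples")
    if (stats::sd(beta_row[ok]) == 0 || stats::sd(expr_row[ok]) == 0)
        stop("constant vector: correlation undefined")
    r <- stats::cor(beta_row[ok], expr_row[ok])
    list(r = r, p = .pearson_p(r, n), n = n)
}

#' Count genes belonging to an annotated set
#'
#' @param genes character vector of gene ids (e.g. a top-k list).
#' @param gene_set character vector defining the set.
#' @return integer size of the intersection.
#' @export
countInGeneSet <- function(genes, gene_set) {
    length(intersect(unique(genes), unique(gene_set)))
}

#' Random-signature (simulated prognostic model) permutation null
#'
#' Repeats `nRep` times: draw `panelSize` markers uniformly without
#' replacement from the candidate list, fit a multivariate Cox model,
#' score the samples, take the `topK` genes most positively correlated
#' with the random risk score, and count how many fall in `gene_set`.
#' The distribution of counts is the permutation null against which the
#' real signature's gene-set count is compared; significance is the
#' empirical upper-tail proportion of null counts reaching an observed
#' count.
#'
#' @param x tumor beta matrix or [MethylationExperiment-class].
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param expr genes x samples expression matrix (same samples).
#' @param candidate_markers marker ids to draw panels from.
#' @param gene_set character vector of annotated gene ids.
#' @param nRep repetitions; default 100.
#' @param panelSize markers per random panel; default 4.
#' @param topK genes taken from the positive correlation ranking; default
#'   10.
#' @param seed RNG seed.
#' @param observed optional observed count; when given, the empirical
#'   upper-tail proportion `mean(counts >= observed)` is reported.
#' @return list `counts` (length nRep), `mean`, `histogram` (table), and
#'   `p_upper` when `observed` is supplied.
#' @export
spmNull <- function(x, surv, expr, candidate_markers, gene_set,
                    nRep = 100, panelSize = 4, topK = 10, seed = 1,
                    observed = NULL) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    expr <- as.matrix(expr)
    if (length(candidate_markers) < panelSize)
        stop("candidate list smaller than the panel size")
    counts <- integer(nRep)
    budget <- 10L
    .with_seed(seed, {
        for (rep in seq_len(nRep)) {
            model <- NULL
            for (try in seq_len(budget)) {
                panel <- sample(candidate_markers, panelSize)
                model <- tryCatch(
                    fitMultivariateCox(beta, surv, panel),
                    error = function(e) NULL)
                if (!is.null(model)) break
            }
            if (is.null(model))
                stop("Cox fits failed repeatedly (", budget,
                     " retries) at repetition ", rep)
            sc <- riskScores(model, beta)
            # top-k by correlation, regardless of significance: the null
            # panel must always yield a full list
            r <- as.numeric(stats::cor(sc, t(expr)))
            top <- rownames(expr)[order(-r)][seq_len(min(topK, nrow(expr)))]
            counts[rep] <- countInGeneSet(top, gene_set)
        }
    })
    out <- list(counts = counts, mean = mean(counts),
                histogram = table(counts))
    if (!is.null(observed))
        out$p_upper <- mean(counts >= observed)
    out
}

#' Two-group prognosis of an expression panel by hierarchical clustering
#'
#' Samples are clustered on the per-gene standardized expression of a
#' small panel (Euclidean distance, Ward linkage) and cut into two
#' groups. The group with the lower mean standardized panel expression is
#' labelled `"low"`. Reports the average observed survival time of
#' deceased patients (AST) per group and the Kaplan-Meier / log-rank
#' comparison.
#'
#' @param expr_panel panel genes x samples expression matrix (>= 2 genes).
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @return list `groups` (`"low"`/`"high"` per sample), `ast` (named
#'   numeric, mean OS of deceased per group; `NaN` when a group has no
#'   deaths), `km` (from [kmLogrank()]), `hclust` (the tree).
#' @export
panelClusterPrognosis <- function(expr_panel, surv) {
    expr_panel <- as.matrix(expr_panel)
    if (nrow(expr_panel) < 2) stop("panel must contain at least 2 genes")
    surv <- .surv_align(surv, colnames(expr_panel))
    sds <- apply(expr_panel, 1, stats::sd)
    if (all(sds == 0))
        stop("degenerate panel: all genes constant across samples")
    z <- expr_panel[sds > 0, , drop = FALSE]
    z <- t(scale(t(z)))
    hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
    cl <- stats::cutree(hc, k = 2)
    if (min(table(cl)) < 2)
        stop("degenerate clustering: a group has fewer than 2 samples")
    mean1 <- mean(z[, cl == 1]); mean2 <- mean(z[, cl == 2])
    lab <- if (mean1 <= mean2) c("low", "high") else c("high", "low")
    groups <- stats::setNames(lab[cl], colnames(expr_panel))
    dead <- surv$os_status == 1
    ast <- vapply(c(low = "low", high = "high"), function(gname)
        mean(surv$os_time[dead & groups == gname]), numeric(1))
    km <- kmLogrank(factor(groups, levels = c("low", "high")), surv)
    list(groups = groups, ast = ast, km = km, hclust = hc)
}
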
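#' Configuration for the synthetic methylation-survival cohort generator
#'
#' The generator emulates an Illumina-450K-like tumor/normal study:
#' beta-distributed marker values (method-of-moments parameterization),
#' planted hyper-/hypomethylated differential markers, planted
#' survival-associated markers driving an exponential proportional-hazards
#' model, completely-at-random missing values, sex-chromosome and
#' multi-mapping probes, and an expression matrix with genes correlated to
#' a per-sample risk score.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_markers total number of methylation markers.
#' @param n_diff_markers number of planted differential markers
#'   (alternating hyper/hypo in tumor).
#' @param diff_delta mean tumor-normal beta separation of planted
#'   differential markers, in \[0,1\].
#' @param marker_sd within-group beta SD of differential and null markers.
#' @param n_prog_markers number of planted survival-associated markers.
#' @param prog_log_hr per-marker log hazard ratio per unit beta; recycled
#'   to `n_prog_markers`.
#' @param prog_marker_sd within-group beta SD of the planted prognostic
#'   markers (larger than `marker_sd`: variably methylated sites carry the
#'   survival signal).
#' @param baseline_hazard exponential baseline hazard, events per time unit.
#' @param censor_rate expected fraction of tumor samples censored, in \[0,1\].
#' @param missing_rate fraction of beta entries set missing, in \[0,1\].
#' @param frac_sex_chrom,frac_multimap fractions of markers flagged as
#'   sex-chromosome / non-uniquely-mapping in the manifest.
#' @param n_genes,n_corr_genes expression matrix size and number of genes
#'   with planted correlation to the risk score (half positive, half
#'   negative).
#' @param corr_strength target population Pearson correlation of planted
#'   genes, in \[-1,1\].
#' @param seed integer RNG seed; every generator draw flows from it.
#'
#' @return a validated `CohortConfig` list.
#' @examples
#' cfg <- cohortConfig(n_tumor = 20, n_normal = 10, n_markers = 100)
#' @export
cohortConfig <- function(n_tumor = 200, n_normal = 50, n_markers = 2000,
                         n_diff_markers = 5, diff_delta = 0.4,
                         marker_sd = 0.05, n_prog_markers = 4,
                         prog_log_hr = c(1.5, 1, 1, -1.2),
                         prog_marker_sd = 0.45, baseline_hazard = 0.08,
                         censor_rate = 0.35, missing_rate = 0.02,
                         frac_sex_chrom = 0.02, frac_multimap = 0.01,
                         n_genes = 1000, n_corr_genes = 10,
                         corr_strength = 0.9, seed = 1L) {
    cfg <- list(n_tumor = n_tumor, n_normal = n_normal,
                n_markers = n_markers, n_diff_markers = n_diff_markers,
                diff_delta = diff_delta, marker_sd = marker_sd,
                n_prog_markers = n_prog_markers,
                prog_log_hr = rep_len(prog_log_hr, max(n_prog_markers, 1L)),
                prog_marker_sd = prog_marker_sd,
                baseline_hazard = baseline_hazard,
                censor_rate = censor_rate, missing_rate = missing_rate,
                frac_sex_chrom = frac_sex_chrom,
                frac_multimap = frac_multimap, n_genes = n_genes,
                n_corr_genes = n_corr_genes, corr_strength = corr_strength,
                seed = seed)
    class(cfg) <- "CohortConfig"
    validateCohortConfig(cfg)
    cfg
}

#' Validate a cohort configuration
#'
#' Checks field types and the joint feasibility constraints (planted marker
#' counts fit into the matrix; planted beta means stay inside (0,1) at the
#' configured separation and spread).
#'
#' @param cfg a `CohortConfig`.
#' @return `cfg`, invisibly; stops with the offending field name otherwise.
#' @export
validateCohortConfig <- function(cfg) {
    for (f in c("n_tumor", "n_normal", "n_markers", "n_diff_markers",
                "n_prog_markers", "n_genes", "n_corr_genes"))
        if (!.is_count(cfg[[f]]))
            stop("invalid CohortConfig field '", f,
                 "': must be a non-negative count")
    for (f in c("censor_rate", "missing_rate", "frac_sex_chrom",
                "frac_multimap", "diff_delta"))
        if (!.is_frac(cfg[[f]]))
            stop("invalid CohortConfig field '", f, "': must be in [0, 1]")
    if (cfg$n_tumor < 1) stop("invalid CohortConfig field 'n_tumor'")
    if (cfg$marker_sd <= 0 || cfg$prog_marker_sd <= 0)
        stop("invalid CohortConfig field 'marker_sd': must be positive")
    if (abs(cfg$corr_strength) > 1)
        stop("invalid CohortConfig field 'corr_strength': must be in [-1, 1]")
    if (cfg$baseline_hazard <= 0)
        stop("invalid CohortConfig field 'baseline_hazard'")
    if (cfg$n_diff_markers + cfg$n_prog_markers > cfg$n_markers)
        stop("invalid CohortConfig field 'n_markers': planted markers ",
             "exceed the total")
    # planted diff means sit at 0.5 +/- diff_delta/2; beta MoM needs
    # sd^2 < mu (1 - mu) at the extreme mean
    mu_min <- 0.5 - cfg$diff_delta / 2
    if (cfg$n_diff_markers > 0 &&
        cfg$marker_sd^2 >= mu_min * (1 - mu_min))
        stop("invalid CohortConfig field 'diff_delta': planted means ",
             "infeasible at this marker_sd (need sd^2 < mu*(1-mu))")
    if (cfg$prog_marker_sd^2 >= 0.25)
        stop("invalid CohortConfig field 'prog_marker_sd': must be < 0.5")
    if (cfg$n_corr_genes > cfg$n_genes)
        stop("invalid CohortConfig field 'n_corr_genes': exceeds n_genes")
    invisible(cfg)
}

#' Simulate a methylation cohort
#'
#' Draws a markers x samples beta matrix. Null markers share one beta
#' distribution across groups (mean uniform on \[0.15, 0.85\], SD
#' `marker_sd`). Planted differential markers have group means
#' 0.5 +/- `diff_delta`/2, alternating hyper/hypo. Planted prognostic
#' markers are variably methylated (mean 0.5, SD `prog_marker_sd`) in both
#' groups; their survival effect is added by [simulateSurvival()]. Missing
#' entries are set completely at random at `missing_rate`; the manifest
#' flags `frac_sex_chrom` markers as chrX/chrY and `frac_multimap` as
#' non-uniquely mapping (planted markers are always autosomal and unique).
#'
#' @param config a [cohortConfig()].
#' @return a [MethylationExperiment-class]; `metadata(x)$truth` records the
#'   planted marker ids, directions and log hazard ratios, and
#'   `metadata(x)$beta_complete` keeps the pre-missingness matrix used by
#'   [simulateSurvival()].
#' @examples
#' me <- simulateMethylation(cohortConfig(n_tumor = 20, n_normal = 10,
#'                                        n_markers = 50, seed = 7))
#' me
#' @export
simulateMethylation <- function(config) {
    validateCohortConfig(config)
    cfg <- config
    .with_seed(.derive_seed(cfg$seed, 1), {
        n <- cfg$n_tumor + cfg$n_normal
        marker_ids <- sprintf("cg%07d", seq_len(cfg$n_markers))
        sample_ids <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                        sprintf("N%03d", seq_len(cfg$n_normal)))
        group <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
        is_t <- group == "tumor"

        idx_diff <- seq_len(cfg$n_diff_markers)
        idx_prog <- cfg$n_diff_markers + seq_len(cfg$n_prog_markers)
        idx_plant <- c(idx_diff, idx_prog)

        # group means per marker
        mu_t <- mu_n <- stats::runif(cfg$n_markers, 0.15, 0.85)
        sd_m <- rep(cfg$marker_sd, cfg$n_markers)
        dir_diff <- character(0)
        if (cfg$n_diff_markers > 0) {
            dir_diff <- rep(c("hyper", "hypo"),
                            length.out = cfg$n_diff_markers)
            hyper <- dir_diff == "hyper"
            mu_t[idx_diff] <- ifelse(hyper, 0.5 + cfg$diff_delta / 2,
                                            0.5 - cfg$diff_delta / 2)
            mu_n[idx_diff] <- ifelse(hyper, 0.5 - cfg$diff_delta / 2,
                                            0.5 + cfg$diff_delta / 2)
        }
        if (cfg$n_prog_markers > 0) {
            mu_t[idx_prog] <- 0.5
            mu_n[idx_prog] <- 0.5
            sd_m[idx_prog] <- cfg$prog_marker_sd
        }

        beta <- matrix(NA_real_, cfg$n_markers, n,
                       dimnames = list(marker_ids, sample_ids))
        for (g in c("tumor", "normal")) {
            cols <- if (g == "tumor") is_t else !is_t
            mu <- if (g == "tumor") mu_t else mu_n
            sh <- .beta_shapes(mu, sd_m)
            beta[, cols] <- stats::rbeta(cfg$n_markers * sum(cols),
                                         shape1 = rep(sh$a, sum(cols)),
                                         shape2 = rep(sh$b, sum(cols)))
        }
        beta_complete <- beta
        if (cfg$missing_rate > 0) {
            drop <- stats::runif(length(beta)) < cfg$missing_rate
            beta[drop] <- NA_real_
        }

        # manifest: sex-chromosome and multi-mapping flags on non-planted
        # markers only
        n_sex <- round(cfg$frac_sex_chrom * cfg$n_markers)
        n_mm <- round(cfg$frac_multimap * cfg$n_markers)
        pool <- setdiff(seq_len(cfg$n_markers), idx_plant)
        if (n_sex + n_mm > length(pool))
            stop("not enough non-planted markers for manifest flags")
        flagged <- sample(pool, n_sex + n_mm)
        idx_sex <- flagged[seq_len(n_sex)]
        idx_mm <- flagged[n_sex + seq_len(n_mm)]
        chrom <- paste0("chr", sample(1:22, cfg$n_markers, replace = TRUE))
        chrom[idx_sex] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
        manifest <- data.frame(marker_id = marker_ids, chrom = chrom,
                               unique_mapping = TRUE)
        manifest$unique_mapping[idx_mm] <- FALSE

        truth <- list(
            diff = data.frame(marker_id = marker_ids[idx_diff],
                              direction = dir_diff,
                              stringsAsFactors = FALSE),
            prog = data.frame(marker_id = marker_ids[idx_prog],
                              log_hr = cfg$prog_log_hr[
                                  seq_len(cfg$n_prog_markers)],
                              stringsAsFactors = FALSE))

        annotation <- data.frame(sample_id = sample_ids, group = group,
                                 stringsAsFactors = FALSE)
        MethylationExperiment(beta, manifest, annotation,
                              metadata = list(truth = truth,
                                              beta_complete = beta_complete,
                                              config = cfg))
    })
}

#' Simulate overall survival for the tumor samples
#'
#' Event times follow an exponential proportional-hazards model with hazard
#' `baseline_hazard * exp(sum(log_hr * beta))` over the planted prognostic
#' markers. Censoring is independent: each sample draws an exponential
#' censoring time with hazard `h * censor_rate / (1 - censor_rate)`, so the
#' probability of being censored is exactly `censor_rate`; ties resolve as
#' events. `censor_rate = 1` censors everyone.
#'
#' @param me a [MethylationExperiment-class] from [simulateMethylation()].
#' @param config the same [cohortConfig()].
#' @return `me` with `os_time` / `os_status` added to `colData()` for tumor
#'   samples (`NA` for normals).
#' @export
simulateSurvival <- function(me, config) {
    validateCohortConfig(config)
    cfg <- config
    groups <- sampleGroups(me)
    if (!any(groups == "tumor")) stop("no tumor samples in the cohort")
    truth <- S4Vectors::metadata(me)$truth
    beta <- S4Vectors::metadata(me)$beta_complete
    if (is.null(beta)) beta <- betaValues(me)
    prog <- truth$prog
    if (!is.null(prog) && nrow(prog) > 0 &&
        !all(prog$marker_id %in% rownames(beta)))
        stop("planted prognostic markers absent from the beta matrix")
    .with_seed(.derive_seed(cfg$seed, 2), {
        tum <- which(groups == "tumor")
        lp <- rep(0, length(tum))
        if (!is.null(prog) && nrow(prog) > 0) {
            b <- beta[prog$marker_id, tum, drop = FALSE]
            # fill any masked entries with the marker median for the hazard
            if (anyNA(b)) {
                med <- apply(b, 1, stats::median, na.rm = TRUE)
                for (i in seq_len(nrow(b)))
                    b[i, is.na(b[i, ])] <- med[i]
            }
            lp <- as.numeric(crossprod(b, prog$log_hr))
        }
        h <- cfg$baseline_hazard * exp(lp)
        tev <- stats::rexp(length(tum), rate = h)
        if (cfg$censor_rate >= 1) {
            time <- tev; status <- 0L
        } else if (cfg$censor_rate <= 0) {
            time <- tev; status <- 1L
        } else {
            hc <- h * cfg$censor_rate / (1 - cfg$censor_rate)
            tc <- stats::rexp(length(tum), rate = hc)
            time <- pmin(tev, tc)
            status <- as.integer(tev <= tc)
        }
        cd <- SummarizedExperiment::colData(me)
        cd$os_time <- NA_real_
        cd$os_status <- NA_integer_
        cd$os_time[tum] <- time
        cd$os_status[tum] <- status
        SummarizedExperiment::colData(me) <- cd
        me
    })
}

#' Simulate a gene-expression matrix correlated with a risk score
#'
#' `n_corr_genes` genes are generated with population Pearson correlation
#' `corr_strength` to the supplied score (half positive, half negative:
#' `x = +/- r z + sqrt(1 - r^2) e` on the standardized score `z`); the
#' remaining genes are independent Gaussian noise. All genes get a baseline
#' mean of 5 and unit scale, standing in for pre-normalized expression.
#'
#' @param scores named numeric vector, one score per (tumor) sample.
#' @param config a [cohortConfig()].
#' @return list with `expression` (genes x samples matrix) and `truth`
#'   (data.frame `gene_id`, `sign` for the planted genes).
#' @export
simulateExpression <- function(scores, config) {
    validateCohortConfig(config)
    cfg <- config
    if (abs(cfg$corr_strength) > 1)
        stop("corr_strength must be in [-1, 1]")
    if (is.null(names(scores)))
        stop("scores must be named by sample id")
    .with_seed(.derive_seed(cfg$seed, 3), {
        n <- length(scores)
        gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
        z <- as.numeric(scale(scores))
        if (any(!is.finite(z))) z <- rep(0, n)  # constant score degenerates
        r <- cfg$corr_strength
        expr <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                       dimnames = list(gene_ids, names(scores)))
        sgn <- integer(0)
        if (cfg$n_corr_genes > 0) {
            sgn <- rep(c(1L, -1L), length.out = cfg$n_corr_genes)
            for (j in seq_len(cfg$n_corr_genes))
                expr[j, ] <- sgn[j] * r * z +
                    sqrt(max(0, 1 - r^2)) * expr[j, ]
        }
        expr <- expr + 5
        list(expression = expr,
             truth = data.frame(gene_id = gene_ids[seq_len(cfg$n_corr_genes)],
                                sign = sgn, stringsAsFactors = FALSE))
    })
}

#' Simulate a complete cohort (methylation + survival + expression)
#'
#' Convenience wrapper chaining [simulateMethylation()],
#' [simulateSurvival()] and [simulateExpression()]; the expression matrix is
#' correlated with the true prognostic linear predictor of the tumor
#' samples.
#'
#' @param config a [cohortConfig()].
#' @return list with `methylation` (a [MethylationExperiment-class] with
#'   survival in `colData`), `expression` (genes x tumor samples), and
#'   `truth` (planted differential markers, prognostic markers, correlated
#'   genes).
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_tumor = 30, n_normal = 10,
#'                                       n_markers = 100, n_genes = 50,
#'                                       seed = 3))
#' names(cohort)
#' @export
simulateCohort <- function(config = cohortConfig()) {
    me <- simulateMethylation(config)
    me <- simulateSurvival(me, config)
    truth <- S4Vectors::metadata(me)$truth
    groups <- sampleGroups(me)
    tum <- names(groups)[groups == "tumor"]
    beta <- S4Vectors::metadata(me)$beta_complete
    lp <- rep(0, length(tum))
    if (nrow(truth$prog) > 0)
        lp <- as.numeric(crossprod(beta[truth$prog$marker_id, tum,
                                        drop = FALSE], truth$prog$log_hr))
    names(lp) <- tum
    ex <- simulateExpression(lp, config)
    truth$corr_genes <- ex$truth
    list(methylation = me, expression = ex$expression, truth = truth)
}
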
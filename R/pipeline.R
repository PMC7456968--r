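#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage threshold with its default value: the diagnostic
#' preselection gates (Ave > 0.3, |log2FC| > 1, FDR < 0.01, SD < 0.2),
#' the prognostic Ave_T > 0.2 filter, the survival fold-change bounds
#' (2, 0.5), the univariate Cox alpha (0.01), the ROC horizons (1, 2, 3
#' time units, documented as years), the subsampling simulation count
#' (100), the SPM repetition count (100), panel size (4) and top-k (10).
#'
#' @param cohort a [cohortConfig()] for the simulated inputs.
#' @param seed master seed; every stochastic stage derives its own
#'   substream from it.
#' @param ... overrides for any listed threshold.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(cohort = cohortConfig(), seed = 1, ...) {
    cfg <- list(cohort = cohort, seed = seed,
                availability_min = 0.9,
                diag_ave_min = 0.3, diag_lfc_min = 1, diag_fdr_max = 0.01,
                diag_sd_max = 0.2, n_sim = 100, k_max = 50,
                prog_ave_min = 0.2, fc_hi = 2, fc_lo = 0.5, alpha = 0.01,
                horizons = c(1, 2, 3), train_frac = 2 / 3,
                n_rep = 100, panel_size = 4, top_k = 10, p_corr = 0.001)
    dots <- list(...)
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
        stop("unknown RunConfig field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
    class(cfg) <- "RunConfig"
    cfg
}

.write_json <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null")

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> preprocess -> differential methylation ->
#' diagnostic signature (train/evaluate) -> prognostic cascade
#' (train/evaluate) -> expression correlation and SPM null, writing every
#' artifact as delimited text/JSON into `outDir` along with a manifest
#' (input checksums, configuration, seed, package version, per-stage
#' counts).
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if needed).
#' @param resume when TRUE, a stage whose declared outputs already exist
#'   is skipped and its outputs are reloaded; deleting an intermediate
#'   file re-runs that stage and everything downstream.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
runPipeline <- function(config = runConfig(), outDir, resume = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(outDir, ...)
    log <- function(...) message("[pipeline] ", ...)
    # once a stage actually runs, everything downstream reruns too
    dirty <- FALSE
    stage_done <- function(files) {
        done <- resume && !dirty && all(file.exists(p(files)))
        if (!done) dirty <<- TRUE
        done
    }

    # stage 1: simulate ---------------------------------------------------
    sim_files <- c("beta.tsv", "manifest.tsv", "annotation.tsv",
                   "expression.tsv", "truth.json")
    if (!stage_done(sim_files)) {
        log("simulate: generating synthetic cohort")
        cohort <- simulateCohort(config$cohort)
        me <- cohort$methylation
        writeBetaMatrix(me, p("beta.tsv"))
        writeProbeManifest(probeManifest(me), p("manifest.tsv"))
        cd <- SummarizedExperiment::colData(me)
        writeSampleAnnotation(
            data.frame(sample_id = colnames(me), group = cd$group,
                       os_time = cd$os_time, os_status = cd$os_status),
            p("annotation.tsv"))
        writeExpressionMatrix(cohort$expression, p("expression.tsv"))
        .write_json(cohort$truth, p("truth.json"))
    } else log("simulate: outputs present, skipped")
    beta <- readBetaMatrix(p("beta.tsv"))
    manifest <- readProbeManifest(p("manifest.tsv"))
    annot <- readSampleAnnotation(p("annotation.tsv"))
    expr <- readExpressionMatrix(p("expression.tsv"))
    me <- MethylationExperiment(beta, manifest, annot)

    # stage 2: preprocess -------------------------------------------------
    if (!stage_done(c("beta_norm.tsv", "filter_report.json"))) {
        log("preprocess: filter / impute / normalize")
        filt <- filterProbes(me, availabilityMin = config$availability_min)
        report <- S4Vectors::metadata(filt)$filter_report
        norm <- normalizeBetweenSamples(imputeMissing(filt))
        writeBetaMatrix(norm, p("beta_norm.tsv"))
        .write_json(report, p("filter_report.json"))
        log("preprocess: retained ", report$n_retained, " of ",
            report$n_input, " markers")
    } else log("preprocess: outputs present, skipped")
    bnorm <- readBetaMatrix(p("beta_norm.tsv"))
    groups <- stats::setNames(annot$group, annot$sample_id)[colnames(bnorm)]

    # stage 3: differential methylation ----------------------------------
    if (!stage_done("marker_stats.tsv")) {
        log("diffmeth: per-marker statistics")
        stats_df <- computeMarkerStats(bnorm, groups)
        utils::write.table(stats_df, p("marker_stats.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    } else log("diffmeth: outputs present, skipped")
    stats_df <- .read_delim_auto(p("marker_stats.tsv"))

    # stage 4: diagnostic signature ---------------------------------------
    if (!stage_done(c("signature.json", "diag_eval.json"))) {
        log("diag: preselect / rank / size-select / fit / evaluate")
        split <- trainTestSplit(groups, frac = config$train_frac,
                                seed = .derive_seed(config$seed, 41))
        pre <- preselectDiagnosticCandidates(
            stats_df, config$diag_ave_min, config$diag_lfc_min,
            config$diag_fdr_max, config$diag_sd_max)
        if (!length(pre$marker_ids))
            stop("diag stage: no candidates pass preselection")
        btr <- bnorm[, split$train, drop = FALSE]
        gtr <- groups[split$train]
        ranked <- rankDiagnosticCandidates(btr, stats_df, pre$marker_ids,
                                           gtr)
        kmax <- min(config$k_max, nrow(ranked))
        sel <- selectSignatureSize(btr, ranked, nSim = config$n_sim,
                                   kMax = kmax,
                                   seed = .derive_seed(config$seed, 42),
                                   groups = gtr)
        sig <- fitDiagnostic(btr, ranked, sel$k_star, gtr)
        writeSignature(sig, p("signature.json"))
        bte <- bnorm[, split$test, drop = FALSE]
        ev <- evaluateDiagnostic(classifySamples(bte, sig),
                                 groups[split$test],
                                 classScores(bte, signatureMarkers(sig),
                                             sig@k))
        .write_json(list(n_candidates = length(pre$marker_ids),
                         k_star = sel$k_star, mean_ba = sel$mean_ba,
                         test = ev[c("sensitivity", "specificity", "ba",
                                     "auc")]),
                    p("diag_eval.json"))
        log("diag: ", length(pre$marker_ids), " candidates -> k* = ",
            sel$k_star)
    } else log("diag: outputs present, skipped")
    sig <- readSignature(p("signature.json"))

    # stage 5: prognostic cascade -----------------------------------------
    if (!stage_done(c("model.json", "prog_eval.json", "screen.tsv"))) {
        log("prog: screen cascade / LASSO / Cox / evaluate")
        tum <- names(groups)[groups == "tumor"]
        surv <- data.frame(sample_id = annot$sample_id,
                           os_time = annot$os_time,
                           os_status = annot$os_status)
        surv <- surv[surv$sample_id %in% tum & !is.na(surv$os_time), ]
        tsplit <- trainTestSplit(rep("tumor", length(surv$sample_id)),
                                 frac = config$train_frac,
                                 seed = .derive_seed(config$seed, 51))
        str_ids <- surv$sample_id[tsplit$train]
        sts_ids <- surv$sample_id[tsplit$test]
        btr <- bnorm[, str_ids, drop = FALSE]
        cas <- prognosticCascade(
            btr, surv, stats = NULL, minAveT = config$prog_ave_min,
            fcHi = config$fc_hi, fcLo = config$fc_lo,
            alpha = config$alpha,
            seed = .derive_seed(config$seed, 52))
        writePrognosticModel(cas$model, p("model.json"))
        utils::write.table(cas$screen, p("screen.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        bte <- bnorm[, sts_ids, drop = FALSE]
        ste <- surv[match(sts_ids, surv$sample_id), ]
        scores <- riskScores(cas$model, bte)
        km <- tryCatch(
            kmLogrank(factor(assignRiskGroups(scores, cas$model),
                             levels = c("low", "high")), ste),
            error = function(e) NULL)
        auc <- timeDependentAUC(scores, ste, config$horizons)
        .write_json(list(
            stage_counts = lapply(cas$stages, length),
            lambda = cas$lambda,
            test = list(hr = if (!is.null(km)) km$hr else NA,
                        logrank_p = if (!is.null(km)) km$p else NA,
                        auc = stats::setNames(as.list(auc$auc),
                                              paste0("t", auc$horizon)))),
            p("prog_eval.json"))
        log("prog: ", paste(names(cas$stages), vapply(cas$stages, length,
            1L), sep = "=", collapse = " -> "))
    } else log("prog: outputs present, skipped")
    model <- readPrognosticModel(p("model.json"))

    # stage 6: expression correlation + SPM null --------------------------
    if (!stage_done(c("correlation.tsv", "spm_summary.json"))) {
        log("correlate: risk score vs expression; SPM null")
        tum_e <- intersect(colnames(expr), colnames(bnorm))
        scores <- riskScores(model, bnorm[, tum_e, drop = FALSE])
        corr <- correlateScoreWithGenes(scores, expr,
                                        topK = config$top_k,
                                        pMax = config$p_corr)
        utils::write.table(corr$table, p("correlation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        surv <- data.frame(sample_id = annot$sample_id,
                           os_time = annot$os_time,
                           os_status = annot$os_status)
        surv <- surv[surv$sample_id %in% tum_e & !is.na(surv$os_time), ]
        # gene set: the planted correlated genes if truth is available,
        # else the observed top list
        truth <- tryCatch(jsonlite::read_json(p("truth.json"),
                                              simplifyVector = TRUE),
                          error = function(e) NULL)
        gene_set <- if (!is.null(truth$corr_genes$gene_id))
            truth$corr_genes$gene_id else corr$top_positive
        cand <- rownames(bnorm)[rowMeans(bnorm[, surv$sample_id]) >
                                config$prog_ave_min]
        obs <- countInGeneSet(corr$top_positive, gene_set)
        spm <- spmNull(bnorm[, surv$sample_id, drop = FALSE], surv, expr,
                       cand, gene_set, nRep = config$n_rep,
                       panelSize = config$panel_size, topK = config$top_k,
                       seed = .derive_seed(config$seed, 61),
                       observed = obs)
        utils::write.table(data.frame(rep = seq_along(spm$counts),
                                      count = spm$counts),
                           p("spm_counts.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .write_json(list(observed = obs, mean_null = spm$mean,
                         p_upper = spm$p_upper,
                         top_positive = corr$top_positive,
                         top_negative = corr$top_negative),
                    p("spm_summary.json"))
    } else log("correlate: outputs present, skipped")

    # manifest -------------------------------------------------------------
    arts <- list.files(outDir, full.names = FALSE)
    arts <- setdiff(arts, "manifest.json")
    .write_json(list(
        package = as.character(utils::packageVersion("methylSigR")),
        seed = config$seed,
        config = config[setdiff(names(config), "cohort")],
        cohort = unclass(config$cohort),
        checksums = as.list(tools::md5sum(file.path(outDir, arts)))),
        p("manifest.json"))
    log("done: ", length(arts), " artifacts in ", outDir)
    invisible(list(signature = sig, model = model, out_dir = outDir))
}
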
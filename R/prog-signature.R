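#' Mean-methylation prescreen for prognostic candidates
#'
#' Retains markers whose training-tumor mean beta Ave_T strictly exceeds
#' `minAveT` (default 0.2).
#'
#' @param stats data.frame from [computeMarkerStats()] (needs `marker_id`,
#'   `ave_t`).
#' @param minAveT threshold; default 0.2.
#' @return character vector of retained marker ids.
#' @export
meanMethylationFilter <- function(stats, minAveT = 0.2) {
    stats$marker_id[stats$ave_t > minAveT]
}

#' Survival-time fold-change prescreen
#'
#' For each marker: MM is the median beta over tumors; Time_H is the mean
#' observed survival time of deceased patients with beta >= MM, Time_L the
#' same for beta < MM; FC = Time_H / Time_L. Markers with FC > `fcHi` or
#' FC < `fcLo` are kept; markers with zero deaths in either stratum are
#' flagged indeterminate and dropped. Censored patients do not enter
#' Time_H / Time_L (they re-enter at the Cox stage).
#'
#' @param x a [MethylationExperiment-class] or beta matrix restricted to
#'   tumor samples (columns must match `surv$sample_id`).
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param fcHi,fcLo fold-change bounds; defaults 2 and 0.5.
#' @param marker_ids markers to screen; default all rows.
#' @return data.frame `marker_id`, `mm`, `time_h`, `time_l`, `fc`,
#'   `status` (`"kept"`, `"dropped"`, `"indeterminate"`).
#' @export
survivalFCScreen <- function(x, surv, fcHi = 2, fcLo = 0.5,
                             marker_ids = NULL) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    if (sum(surv$os_status == 1) < 1)
        stop("no deaths in the cohort: fold-change screen undefined")
    if (is.null(marker_ids)) marker_ids <- rownames(beta)
    dead <- surv$os_status == 1
    tdead <- surv$os_time[dead]
    out <- lapply(marker_ids, function(m) {
        b <- beta[m, ]
        mm <- stats::median(b)
        hi <- b[dead] >= mm
        nh <- sum(hi); nl <- sum(!hi)
        th <- if (nh) mean(tdead[hi]) else NA_real_
        tl <- if (nl) mean(tdead[!hi]) else NA_real_
        fc <- th / tl
        status <- if (nh == 0 || nl == 0) "indeterminate"
            else if (fc > fcHi || fc < fcLo) "kept" else "dropped"
        data.frame(marker_id = m, mm = mm, time_h = th, time_l = tl,
                   fc = fc, status = status, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Univariate Cox screen
#'
#' Fits a univariate proportional-hazards model of overall survival on
#' each marker's beta (Efron ties) and keeps markers with Wald p <
#' `alpha`. Constant and non-converging markers are dropped with a
#' warning.
#'
#' @param x tumor beta matrix or [MethylationExperiment-class].
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param alpha significance threshold; default 0.01.
#' @param marker_ids markers to screen; default all rows.
#' @return data.frame `marker_id`, `cox_coef`, `cox_p`, `kept`.
#' @export
univariateCoxScreen <- function(x, surv, alpha = 0.01, marker_ids = NULL) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    if (is.null(marker_ids)) marker_ids <- rownames(beta)
    y <- survival::Surv(surv$os_time, surv$os_status)
    dropped <- character(0)
    rows <- lapply(marker_ids, function(m) {
        b <- beta[m, ]
        if (stats::sd(b) == 0) {
            dropped <<- c(dropped, m)
            return(NULL)
        }
        fit <- tryCatch(survival::coxph(y ~ b), error = function(e) NULL)
        if (is.null(fit) || anyNA(stats::coef(fit))) {
            dropped <<- c(dropped, m)
            return(NULL)
        }
        s <- summary(fit)$coefficients
        data.frame(marker_id = m, cox_coef = s[1, "coef"],
                   cox_p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
    })
    if (length(dropped))
        warning(length(dropped),
                " marker(s) dropped (constant or non-converging): ",
                paste(utils::head(dropped, 5), collapse = ", "))
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(marker_id = character(0), cox_coef = numeric(0),
                          cox_p = numeric(0), kept = logical(0)))
    out$kept <- out$cox_p < alpha
    out
}

#' LASSO-Cox marker selection at cross-validated lambda-min
#'
#' L1-penalized Cox regression over the candidate markers; the penalty is
#' chosen to minimize the cross-validated partial-likelihood deviance
#' ("min" lambda). Fold assignment is seeded and stratified by event
#' status.
#'
#' @param x tumor beta matrix or [MethylationExperiment-class].
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param marker_ids candidate markers (>= 2).
#' @param nFolds number of cross-validation folds; default
#'   `min(100, number of events)` (the full leave-groups-out analogue of
#'   100-fold CV degenerates on small cohorts).
#' @param seed RNG seed for fold assignment.
#' @return list `marker_ids` (nonzero-coefficient markers), `lambda`, and
#'   the `cv_fit` object.
#' @export
lassoCoxSelect <- function(x, surv, marker_ids, nFolds = NULL, seed = 1) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    if (length(marker_ids) < 2)
        stop("need at least 2 candidate markers for LASSO selection")
    missing <- setdiff(marker_ids, rownames(beta))
    if (length(missing))
        stop("marker(s) absent from the beta matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    X <- t(beta[marker_ids, , drop = FALSE])
    y <- survival::Surv(surv$os_time, surv$os_status)
    nev <- sum(surv$os_status == 1)
    if (nev < 2) stop("need at least 2 events for cross-validation")
    if (is.null(nFolds)) nFolds <- min(100, nev)
    nFolds <- max(3, min(nFolds, nrow(X)))
    foldid <- integer(nrow(X))
    .with_seed(seed, {
        for (s in c(0, 1)) {
            idx <- which(surv$os_status == s)
            foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
        }
        cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid)
    })
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    sel <- marker_ids[cf != 0]
    if (!length(sel))
        stop("all coefficients shrunk to zero at lambda-min; ",
             "consider a smaller lambda grid")
    list(marker_ids = sel, lambda = cv$lambda.min, cv_fit = cv)
}

#' Fit the multivariate Cox prognostic model
#'
#' Unpenalized multivariate proportional-hazards fit (Efron ties) over the
#' selected markers on raw beta values. The per-sample risk score is the
#' linear predictor `sum(coef_m * beta_m)`; the risk cutoff is the
#' linear-interpolation median of the training risk scores.
#'
#' @param x tumor beta matrix or [MethylationExperiment-class].
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param marker_ids the selected markers.
#' @param lambda optional LASSO penalty to record in the model.
#' @return a [PrognosticModel-class].
#' @export
fitMultivariateCox <- function(x, surv, marker_ids, lambda = NA_real_) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    X <- t(beta[marker_ids, , drop = FALSE])
    if (any(apply(X, 2, stats::sd) == 0))
        stop("constant marker column(s) in the design matrix")
    y <- survival::Surv(surv$os_time, surv$os_status)
    df <- data.frame(X, check.names = FALSE)
    fit <- survival::coxph(y ~ ., data = df, ties = "efron")
    cf <- stats::coef(fit)
    if (anyNA(cf) || any(!is.finite(cf)))
        stop("multivariate Cox fit did not converge ",
             "(singular or separated design); coefficients: ",
             paste(signif(cf, 3), collapse = ", "))
    names(cf) <- marker_ids
    scores <- as.numeric(X %*% cf)
    methods::new("PrognosticModel", coefficients = cf,
                 lambda = as.numeric(lambda),
                 riskCutoff = stats::median(scores))
}

#' Risk scores under a prognostic model
#' @param model a [PrognosticModel-class].
#' @param x beta matrix or [MethylationExperiment-class] containing the
#'   model's markers.
#' @return numeric vector named by sample id.
#' @rdname riskScores
#' @export
setMethod("riskScores", "PrognosticModel", function(model, x) {
    beta <- .beta_of(x)
    cf <- model@coefficients
    missing <- setdiff(names(cf), rownames(beta))
    if (length(missing))
        stop("marker(s) absent from the beta matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    colSums(beta[names(cf), , drop = FALSE] * cf)
})

#' Assign high/low risk groups
#'
#' High-risk iff risk score is greater than or equal to the model's
#' training-median cutoff.
#'
#' @param scores numeric risk scores.
#' @param model a [PrognosticModel-class] (or a numeric cutoff).
#' @return character vector `"high"`/`"low"` named like `scores`.
#' @export
assignRiskGroups <- function(scores, model) {
    cutoff <- if (methods::is(model, "PrognosticModel"))
        model@riskCutoff else as.numeric(model)
    ifelse(scores >= cutoff, "high", "low")
}

#' Kaplan-Meier curves, log-rank test and hazard ratio for two groups
#'
#' Product-limit survival estimates per group, the two-sample log-rank
#' chi-square test, and the hazard ratio of the second level vs the first
#' from a univariate Cox fit on the group indicator with a Wald confidence
#' interval.
#'
#' @param groups two-level factor/character (e.g. `"low"` / `"high"`);
#'   the HR is reported for the second level relative to the first
#'   (with the default levels, high vs low).
#' @param surv data.frame `sample_id`, `os_time`, `os_status` aligned with
#'   `groups` (matched by name when `groups` is named).
#' @return list `fit` (survfit), `chisq`, `p` (log-rank), `hr`,
#'   `hr_lower`, `hr_upper` (95% Wald CI), `n` per group.
#' @export
kmLogrank <- function(groups, surv) {
    surv <- as.data.frame(surv)
    if (!is.null(names(groups)))
        surv <- .surv_align(surv, names(groups))
    if (nrow(surv) != length(groups))
        stop("groups and survival rows differ in length")
    g <- factor(groups)
    if (nlevels(g) != 2 || any(table(g) == 0))
        stop("need exactly two non-empty groups")
    y <- survival::Surv(surv$os_time, surv$os_status)
    fit <- survival::survfit(y ~ g)
    sd <- survival::survdiff(y ~ g)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    cox <- survival::coxph(y ~ g)
    cf <- summary(cox)$coefficients
    ci <- summary(cox)$conf.int
    list(fit = fit, chisq = unname(sd$chisq), p = p,
         hr = unname(ci[1, "exp(coef)"]),
         hr_lower = unname(ci[1, "lower .95"]),
         hr_upper = unname(ci[1, "upper .95"]),
         hr_p = unname(cf[1, "Pr(>|z|)"]),
         n = table(g))
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At horizon t, cases are samples with an observed event by t and
#' controls are samples still at risk beyond t. Discrimination of the
#' score is weighted by the inverse probability of censoring, estimated by
#' the Kaplan-Meier estimator of the censoring distribution: case i gets
#' weight 1/G(T_i-), control j gets 1/G(t). Tied scores receive half
#' credit. With no censoring this reduces to the empirical concordance
#' between the score and the event-by-t indicator.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param surv data.frame `sample_id`, `os_time`, `os_status` aligned with
#'   `scores` (matched by name when `scores` is named).
#' @param horizons numeric vector of evaluation times.
#' @return data.frame `horizon`, `auc`, `n_cases`, `n_controls`,
#'   `defined` (FALSE past the last observed time or when a class is
#'   empty; then `auc` is `NA`).
#' @export
timeDependentAUC <- function(scores, surv, horizons) {
    surv <- as.data.frame(surv)
    if (!is.null(names(scores)))
        surv <- .surv_align(surv, names(scores))
    if (nrow(surv) != length(scores))
        stop("scores and survival rows differ in length")
    tt <- surv$os_time
    dd <- surv$os_status
    # KM estimator of the censoring distribution G
    gfit <- survival::survfit(survival::Surv(tt, 1 - dd) ~ 1)
    G <- function(u) {
        # left-continuous evaluation G(u-) via u - eps on the step grid
        vapply(u, function(ui) {
            s <- gfit$surv[gfit$time < ui - 1e-12]
            if (length(s)) s[length(s)] else 1
        }, numeric(1))
    }
    Gat <- function(u) {
        vapply(u, function(ui) {
            s <- gfit$surv[gfit$time <= ui + 1e-12]
            if (length(s)) s[length(s)] else 1
        }, numeric(1))
    }
    out <- lapply(horizons, function(h) {
        if (h > max(tt))
            return(data.frame(horizon = h, auc = NA_real_, n_cases = 0L,
                              n_controls = 0L, defined = FALSE))
        case <- tt <= h & dd == 1
        ctrl <- tt > h
        if (!any(case) || !any(ctrl))
            return(data.frame(horizon = h, auc = NA_real_,
                              n_cases = sum(case), n_controls = sum(ctrl),
                              defined = FALSE))
        wc <- 1 / G(tt[case])
        wk <- rep(1 / Gat(h), sum(ctrl))
        sc <- scores[case]; sk <- scores[ctrl]
        cmp <- outer(sc, sk, function(a, b)
            (a > b) + 0.5 * (a == b))
        w <- outer(wc, wk)
        data.frame(horizon = h, auc = sum(w * cmp) / sum(w),
                   n_cases = sum(case), n_controls = sum(ctrl),
                   defined = TRUE)
    })
    do.call(rbind, out)
}

#' Stratified evaluation of a prognostic model
#'
#' Within each level of a clinical stratum: risk groups by the model's
#' global training cutoff, Kaplan-Meier / log-rank / HR, and the
#' time-dependent AUC at one horizon. Levels smaller than `minSize` are
#' skipped with a note.
#'
#' @param model a [PrognosticModel-class].
#' @param x tumor beta matrix or [MethylationExperiment-class].
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param strata vector of stratum labels aligned with the samples.
#' @param horizon AUC evaluation time; default 1.
#' @param minSize minimum stratum size; default 20.
#' @return named list per level: either `skipped = TRUE` with the size, or
#'   `km` (from [kmLogrank()]) and `auc`.
#' @export
stratifiedEvaluation <- function(model, x, surv, strata, horizon = 1,
                                 minSize = 20) {
    beta <- .beta_of(x)
    surv <- .surv_align(surv, colnames(beta))
    if (length(strata) != ncol(beta))
        stop("strata length does not match the number of samples")
    scores <- riskScores(model, beta)
    out <- list()
    for (lev in unique(as.character(strata))) {
        idx <- which(strata == lev)
        if (length(idx) < minSize) {
            out[[lev]] <- list(skipped = TRUE, n = length(idx))
            next
        }
        g <- assignRiskGroups(scores[idx], model)
        s <- surv[idx, , drop = FALSE]
        km <- tryCatch(kmLogrank(factor(g, levels = c("low", "high")), s),
                       error = function(e) NULL)
        auc <- timeDependentAUC(scores[idx], s, horizon)
        out[[lev]] <- list(skipped = FALSE, n = length(idx), km = km,
                           auc = auc$auc[1])
    }
    out
}

#' Seeded stratified train/validation split
#'
#' Splits samples into a training fraction and its complement, stratified
#' by group label so tumors and normals split at the same rate.
#'
#' @param groups `"tumor"`/`"normal"` labels (or any labels) per sample.
#' @param frac training fraction; default 2/3.
#' @param seed RNG seed.
#' @return list `train`, `test` of integer indices.
#' @export
trainTestSplit <- function(groups, frac = 2 / 3, seed = 1) {
    if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
    train <- integer(0)
    .with_seed(seed, {
        for (lev in unique(as.character(groups))) {
            idx <- which(groups == lev)
            train <- c(train, sample(idx, round(frac * length(idx))))
        }
    })
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(groups), train))
}

#' Run the full prognostic screening cascade
#'
#' Ave_T filter -> survival fold-change screen -> univariate Cox ->
#' LASSO-Cox at lambda-min -> multivariate Cox model, mirroring the
#' candidate-narrowing cascade; each stage's candidate set nests inside
#' the previous one.
#'
#' @param x tumor beta matrix or [MethylationExperiment-class] (tumor
#'   samples only).
#' @param surv data.frame `sample_id`, `os_time`, `os_status`.
#' @param stats marker statistics from [computeMarkerStats()] (for Ave_T);
#'   when `NULL`, Ave_T is computed from `x` directly.
#' @param minAveT,fcHi,fcLo,alpha stage thresholds (defaults 0.2, 2, 0.5,
#'   0.01).
#' @param nFolds,seed LASSO cross-validation parameters.
#' @return list `model` (a [PrognosticModel-class]), `stages` (named list
#'   of candidate marker-id vectors per stage), `screen` (the fold-change
#'   screen table), `cox` (the univariate screen table), `lambda`.
#' @export
prognosticCascade <- function(x, surv, stats = NULL, minAveT = 0.2,
                              fcHi = 2, fcLo = 0.5, alpha = 0.01,
                              nFolds = NULL, seed = 1) {
    beta <- .beta_of(x)
    if (is.null(stats)) {
        ave_t <- rowMeans(beta)
        stats <- data.frame(marker_id = rownames(beta), ave_t = ave_t,
                            stringsAsFactors = FALSE)
    }
    s1 <- meanMethylationFilter(stats, minAveT)
    s1 <- intersect(s1, rownames(beta))
    if (!length(s1)) stop("no markers pass the Ave_T filter")
    screen <- survivalFCScreen(beta[s1, , drop = FALSE], surv,
                               fcHi = fcHi, fcLo = fcLo)
    s2 <- screen$marker_id[screen$status == "kept"]
    if (!length(s2)) stop("no markers pass the survival FC screen")
    cox <- univariateCoxScreen(beta[s2, , drop = FALSE], surv,
                               alpha = alpha)
    s3 <- cox$marker_id[cox$kept]
    if (length(s3) < 2)
        stop("fewer than 2 markers pass the univariate Cox screen")
    las <- lassoCoxSelect(beta[s3, , drop = FALSE], surv, s3,
                          nFolds = nFolds, seed = seed)
    model <- fitMultivariateCox(beta, surv, las$marker_ids,
                                lambda = las$lambda)
    list(model = model,
         stages = list(mean_methylation = s1, survival_fc = s2,
                       univariate_cox = s3, lasso = las$marker_ids,
                       final = names(model@coefficients)),
         screen = screen, cox = cox, lambda = las$lambda)
}
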
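test_that("the Ave_T filter is strict at the boundary", {
    st <- data.frame(marker_id = c("a", "b", "c"),
                     ave_t = c(0.2, 0.21, 0.9))
    expect_equal(meanMethylationFilter(st), c("b", "c"))
})

test_that("the survival fold-change screen matches hand computation", {
    b <- tiny_beta(c(0.1, 0.2, 0.8, 0.9), 1, 4)
    s <- surv_df(colnames(b), c(10, 10, 2, 2), c(1, 1, 1, 1))
    out <- survivalFCScreen(b, s)
    expect_equal(out$mm, 0.5)
    expect_equal(out$time_h, 2)
    expect_equal(out$time_l, 10)
    expect_equal(out$fc, 0.2)
    expect_equal(out$status, "kept")
    # equal times: fc = 1, dropped
    s2 <- surv_df(colnames(b), c(5, 5, 5, 5), c(1, 1, 1, 1))
    expect_equal(survivalFCScreen(b, s2)$status, "dropped")
    # all deaths on one side of MM: indeterminate
    s3 <- surv_df(colnames(b), c(10, 10, 2, 2), c(0, 0, 1, 1))
    expect_equal(survivalFCScreen(b, s3)$status, "indeterminate")
    # no deaths at all is an error
    s4 <- surv_df(colnames(b), c(10, 10, 2, 2), c(0, 0, 0, 0))
    expect_error(survivalFCScreen(b, s4), "no deaths")
})

test_that("censored patients are excluded from the death-time means", {
    b <- tiny_beta(c(0.1, 0.2, 0.8, 0.9, 0.85, 0.15), 1, 6)
    s <- surv_df(colnames(b), c(10, 12, 2, 4, 99, 99),
                 c(1, 1, 1, 1, 0, 0))
    out <- survivalFCScreen(b, s)
    expect_equal(out$time_h, 3)   # deaths at beta >= 0.5: times 2, 4
    expect_equal(out$time_l, 11)  # deaths at beta < 0.5: times 10, 12
})

test_that("the univariate Cox screen keeps strong markers and drops constants", {
    set.seed(12)
    n <- 100
    b <- rbind(step = rep(c(0.9, 0.1), each = n / 2),
               flat = rep(0.5, n),
               noise = runif(n))
    colnames(b) <- sprintf("s%03d", 1:n)
    # high-beta samples die much earlier
    s <- surv_df(colnames(b), rexp(n, 0.3 * exp(3 * b["step", ])),
                 rep(1, n))
    expect_warning(out <- univariateCoxScreen(b, s), "constant")
    expect_true(out$kept[out$marker_id == "step"])
    expect_lt(out$cox_p[out$marker_id == "step"], 1e-6)
    expect_false("flat" %in% out$marker_id)
})

test_that("LASSO-Cox selection recovers a strong marker and is seeded", {
    set.seed(30)
    n <- 150
    b <- rbind(strong = runif(n), null1 = runif(n), null2 = runif(n))
    colnames(b) <- sprintf("s%03d", 1:n)
    time <- rexp(n, rate = 0.2 * exp(3 * b["strong", ]))
    s <- surv_df(colnames(b), time, rbinom(n, 1, 0.8))
    sel <- lassoCoxSelect(b, s, rownames(b), seed = 4)
    expect_true("strong" %in% sel$marker_ids)
    sel2 <- lassoCoxSelect(b, s, rownames(b), seed = 4)
    expect_identical(sel$marker_ids, sel2$marker_ids)
    expect_identical(sel$lambda, sel2$lambda)
    expect_error(lassoCoxSelect(b, s, "strong"), "at least 2")
})

test_that("risk scores are the coefficient-weighted beta sums", {
    cf <- c(cg19265480 = 1.557, cg06293745 = 4.321, cg17186803 = 1.556,
            cg08151370 = -1.786)
    model <- new("PrognosticModel", coefficients = cf, lambda = NA_real_,
                 riskCutoff = 3.679)
    b <- tiny_beta(rep(1, 4), 4, 1)
    rownames(b) <- names(cf)
    expect_equal(unname(riskScores(model, b)), 5.648)
    expect_equal(unname(riskScores(model, b * 0)), 0)
    # invariant to marker order; zero-coefficient markers are inert
    b2 <- b[c(3, 1, 4, 2), , drop = FALSE]
    expect_equal(riskScores(model, b2), riskScores(model, b))
    cf0 <- c(cf, cgExtra = 0)
    model0 <- new("PrognosticModel", coefficients = cf0,
                  lambda = NA_real_, riskCutoff = 3.679)
    b3 <- rbind(b, cgExtra = 0.7)
    expect_equal(unname(riskScores(model0, b3)),
                 unname(riskScores(model, b)))
})

test_that("multivariate Cox recovers planted coefficient signs", {
    set.seed(44)
    n <- 500
    b <- rbind(up = runif(n), down = runif(n))
    colnames(b) <- sprintf("s%03d", 1:n)
    time <- rexp(n, 0.2 * exp(1.5 * b["up", ] - 1.0 * b["down", ]))
    s <- surv_df(colnames(b), time, rbinom(n, 1, 0.8))
    model <- fitMultivariateCox(b, s, rownames(b))
    expect_gt(coef(model)[["up"]], 0)
    expect_lt(coef(model)[["down"]], 0)
    expect_equal(model@riskCutoff,
                 median(riskScores(model, b)))
    expect_error(fitMultivariateCox(rbind(b, flat = 0.5), s,
                                    c("up", "flat")), "constant")
})

test_that("risk grouping splits at the median with the boundary in high", {
    cf <- c(m = 1)
    model <- new("PrognosticModel", coefficients = cf, lambda = NA_real_,
                 riskCutoff = 2)
    expect_equal(unname(assignRiskGroups(c(2, 1.999, 2.5), model)),
                 c("high", "low", "high"))
    # median split on distinct training scores differs by at most 1
    set.seed(9)
    sc <- rnorm(101)
    g <- assignRiskGroups(sc, median(sc))
    expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
})

test_that("identical groups give a null log-rank test and HR 1", {
    s <- surv_df(sprintf("s%02d", 1:20),
                 rep(c(1, 2, 3, 4, 6), 4), rep(c(1, 0), 10))
    g <- rep(c("low", "high"), each = 10)  # two identical copies
    s$os_time <- rep(s$os_time[1:10], 2)
    s$os_status <- rep(s$os_status[1:10], 2)
    km <- suppressWarnings(kmLogrank(factor(g, c("low", "high")), s))
    expect_equal(km$chisq, 0, tolerance = 1e-8)
    expect_equal(km$hr, 1, tolerance = 1e-6)
})

test_that("a planted group hazard ratio of 3 is recovered", {
    set.seed(70)
    n <- 300
    g <- rep(c("low", "high"), each = n / 2)
    time <- rexp(n, 0.2 * ifelse(g == "high", 3, 1))
    s <- surv_df(sprintf("s%03d", 1:n), time, rbinom(n, 1, 0.8))
    km <- kmLogrank(factor(g, c("low", "high")), s)
    expect_gt(km$hr, 2)
    expect_lt(km$hr, 4.5)
    expect_lt(km$p, 1e-4)
})

test_that("the log-rank p matches a label-permutation null on a small cohort", {
    set.seed(91)
    n <- 40
    g <- rep(c("low", "high"), each = n / 2)
    time <- rexp(n, 0.3 * ifelse(g == "high", 2.2, 1))
    status <- rbinom(n, 1, 0.85)
    s <- surv_df(sprintf("s%02d", 1:n), time, status)
    km <- kmLogrank(factor(g, c("low", "high")), s)
    y <- survival::Surv(time, status)
    obs <- km$chisq
    perm <- replicate(1500, {
        gp <- sample(g)
        survival::survdiff(y ~ gp)$chisq
    })
    p_perm <- (1 + sum(perm >= obs)) / (1 + length(perm))
    expect_lt(abs(p_perm - km$p), 3 * sqrt(km$p * (1 - km$p) / 1500) + 0.01)
})

test_that("time-dependent AUC is 1 for a perfect ranking and flags bad horizons", {
    n <- 50
    time <- seq(0.1, 5, length.out = n)
    s <- surv_df(sprintf("s%02d", 1:n), time, rep(1, n))
    sc <- -time  # higher risk = earlier death, perfectly
    out <- timeDependentAUC(sc, s, c(1, 2.5, 99))
    expect_equal(out$auc[1:2], c(1, 1))
    expect_false(out$defined[3])
    expect_true(is.na(out$auc[3]))
})

test_that("without censoring the AUC equals direct concordance counting", {
    set.seed(33)
    n <- 120
    time <- rexp(n, 0.4)
    sc <- -log(time) + rnorm(n)
    s <- surv_df(sprintf("s%03d", 1:n), time, rep(1, n))
    for (h in c(0.5, 1, 2)) {
        case <- time <= h
        ctrl <- time > h
        cmp <- outer(sc[case], sc[ctrl],
                     function(a, b) (a > b) + 0.5 * (a == b))
        expect_equal(timeDependentAUC(sc, s, h)$auc, mean(cmp))
    }
})

test_that("stratified evaluation reduces to the pooled analysis for one stratum", {
    set.seed(3)
    n <- 60
    b <- tiny_beta(runif(2 * n), 2, n)
    cf <- c(cg001 = 1.2, cg002 = -0.8)
    time <- rexp(n, 0.3 * exp(as.numeric(cf %*% b)))
    s <- surv_df(colnames(b), time, rbinom(n, 1, 0.8))
    model <- new("PrognosticModel", coefficients = cf, lambda = NA_real_,
                 riskCutoff = median(colSums(b * cf)))
    one <- stratifiedEvaluation(model, b, s, rep("all", n), horizon = 1)
    sc <- riskScores(model, b)
    pooled <- kmLogrank(factor(assignRiskGroups(sc, model),
                               c("low", "high")), s)
    expect_equal(one$all$km$p, pooled$p)
    expect_equal(one$all$auc, timeDependentAUC(sc, s, 1)$auc)
    # small strata are skipped with their size reported
    two <- stratifiedEvaluation(model, b, s,
                                rep(c("big", "tiny"), c(n - 5, 5)),
                                horizon = 1)
    expect_true(two$tiny$skipped)
    expect_equal(two$tiny$n, 5)
})

test_that("the screening cascade yields monotonically nested candidate sets", {
    co <- small_cohort()
    me <- co$methylation
    g <- sampleGroups(me)
    tum <- names(g)[g == "tumor"]
    s <- survivalOutcome(me)
    cas <- prognosticCascade(betaValues(me)[, tum], s, seed = 8)
    st <- cas$stages
    expect_true(all(st$survival_fc %in% st$mean_methylation))
    expect_true(all(st$univariate_cox %in% st$survival_fc))
    expect_true(all(st$lasso %in% st$univariate_cox))
    expect_true(all(st$final %in% st$lasso))
})

test_that("train/test splits are seeded partitions stratified by group", {
    g <- rep(c("tumor", "normal"), c(90, 30))
    sp <- trainTestSplit(g, frac = 2 / 3, seed = 10)
    expect_setequal(c(sp$train, sp$test), seq_along(g))
    expect_equal(sum(g[sp$train] == "tumor"), 60)
    expect_equal(sum(g[sp$train] == "normal"), 20)
    expect_identical(trainTestSplit(g, 2 / 3, seed = 10), sp)
})

test_that("prognostic model JSON round-trip preserves scores", {
    cf <- c(cgA = 1.5, cgB = -2.25)
    model <- new("PrognosticModel", coefficients = cf, lambda = 0.031,
                 riskCutoff = 0.4)
    path <- tempfile(fileext = ".json")
    writePrognosticModel(model, path)
    m2 <- readPrognosticModel(path)
    expect_identical(coef(m2), coef(model))
    expect_identical(m2@riskCutoff, model@riskCutoff)
    expect_identical(m2@lambda, model@lambda)
})
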
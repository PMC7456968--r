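test_that("invalid configurations are rejected naming the field", {
    expect_error(cohortConfig(n_tumor = -1), "n_tumor")
    expect_error(cohortConfig(missing_rate = 1.2), "missing_rate")
    expect_error(cohortConfig(n_markers = 5, n_diff_markers = 4,
                              n_prog_markers = 4), "n_markers")
    expect_error(cohortConfig(corr_strength = 1.5), "corr_strength")
    expect_error(cohortConfig(diff_delta = 0.9, marker_sd = 0.3),
                 "diff_delta")
    expect_error(cohortConfig(n_corr_genes = 20, n_genes = 10),
                 "n_corr_genes")
})

test_that("the generator is bit-identical under a fixed seed", {
    cfg <- cohortConfig(n_tumor = 25, n_normal = 10, n_markers = 120,
                        n_genes = 40, seed = 42)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(betaValues(a$methylation), betaValues(b$methylation))
    expect_identical(survivalOutcome(a$methylation),
                     survivalOutcome(b$methylation))
    expect_identical(a$expression, b$expression)
    expect_identical(a$truth, b$truth)
})

test_that("generated values respect their domains", {
    co <- small_cohort()
    b <- betaValues(co$methylation)
    expect_true(all(b >= 0 & b <= 1, na.rm = TRUE))
    s <- survivalOutcome(co$methylation)
    expect_true(all(s$os_time > 0))
    expect_true(all(s$os_status %in% c(0, 1)))
    man <- probeManifest(co$methylation)
    expect_true(all(!man$marker_id[man$chrom %in% c("chrX", "chrY")] %in%
                    c(co$truth$diff$marker_id, co$truth$prog$marker_id)))
})

test_that("planted differential markers show the configured mean gap", {
    cfg <- cohortConfig(n_tumor = 200, n_normal = 50, n_markers = 400,
                        n_diff_markers = 20, diff_delta = 0.4,
                        marker_sd = 0.05, missing_rate = 0, seed = 9)
    me <- simulateMethylation(cfg)
    b <- betaValues(me)
    g <- sampleGroups(me)
    truth <- S4Vectors::metadata(me)$truth$diff
    gap <- rowMeans(b[truth$marker_id, g == "tumor"]) -
        rowMeans(b[truth$marker_id, g == "normal"])
    signed <- ifelse(truth$direction == "hyper", gap, -gap)
    expect_true(all(abs(signed - 0.4) < 0.05))
})

test_that("without planted effects all mean gaps are within 3 SE of zero", {
    cfg <- cohortConfig(n_tumor = 150, n_normal = 150, n_markers = 300,
                        n_diff_markers = 0, n_prog_markers = 0,
                        marker_sd = 0.05, missing_rate = 0, seed = 13)
    me <- simulateMethylation(cfg)
    b <- betaValues(me)
    g <- sampleGroups(me)
    gap <- rowMeans(b[, g == "tumor"]) - rowMeans(b[, g == "normal"])
    se <- sqrt(apply(b[, g == "tumor"], 1, var) / 150 +
               apply(b[, g == "normal"], 1, var) / 150)
    # 3 SE per marker: expect at most a small number of exceedances by
    # chance (P ~ 0.0027 each)
    expect_lt(mean(abs(gap) > 3 * se), 0.02)
})

test_that("degenerate censoring settings behave as documented", {
    cfg <- cohortConfig(n_tumor = 40, n_normal = 5, n_markers = 50,
                        censor_rate = 1, missing_rate = 0, seed = 3)
    s <- survivalOutcome(simulateSurvival(simulateMethylation(cfg), cfg))
    expect_true(all(s$os_status == 0))
    cfg0 <- cohortConfig(n_tumor = 40, n_normal = 5, n_markers = 50,
                         censor_rate = 0, missing_rate = 0, seed = 3)
    s0 <- survivalOutcome(simulateSurvival(simulateMethylation(cfg0), cfg0))
    expect_true(all(s0$os_status == 1))
})

test_that("a univariate Cox fit recovers a planted log hazard ratio", {
    cfg <- cohortConfig(n_tumor = 500, n_normal = 5, n_markers = 60,
                        n_diff_markers = 0, n_prog_markers = 1,
                        prog_log_hr = 2, censor_rate = 0.2,
                        missing_rate = 0, seed = 21)
    me <- simulateSurvival(simulateMethylation(cfg), cfg)
    s <- survivalOutcome(me)
    b <- betaValues(me)[S4Vectors::metadata(me)$truth$prog$marker_id,
                        s$sample_id]
    fit <- survival::coxph(survival::Surv(s$os_time, s$os_status) ~ b)
    expect_lt(abs(unname(coef(fit)) - 2), 0.3)
})

test_that("censoring fraction matches the configured rate", {
    cfg <- cohortConfig(n_tumor = 800, n_normal = 5, n_markers = 30,
                        n_prog_markers = 2, censor_rate = 0.35,
                        missing_rate = 0, seed = 17)
    s <- survivalOutcome(simulateSurvival(simulateMethylation(cfg), cfg))
    expect_lt(abs(mean(s$os_status == 0) - 0.35), 3 * sqrt(0.35 * 0.65 / 800))
})

test_that("planted expression genes reach the configured correlation", {
    score <- stats::setNames(rnorm(300), sprintf("T%03d", 1:300))
    cfg <- cohortConfig(n_tumor = 300, n_normal = 5, n_markers = 30,
                        n_genes = 200, n_corr_genes = 10,
                        corr_strength = 0.9, seed = 5)
    ex <- simulateExpression(score, cfg)
    r <- as.numeric(cor(score, t(ex$expression[ex$truth$gene_id, ])))
    expect_true(all(abs(r - ex$truth$sign * 0.9) < 0.1))
    # non-planted genes are independent noise
    r0 <- as.numeric(cor(score,
                         t(ex$expression[setdiff(rownames(ex$expression),
                                                 ex$truth$gene_id), ])))
    expect_lt(max(abs(r0)), 4 / sqrt(300))
})

test_that("missingness hits the configured rate and only the observed copy", {
    cfg <- cohortConfig(n_tumor = 100, n_normal = 30, n_markers = 200,
                        missing_rate = 0.05, seed = 7)
    me <- simulateMethylation(cfg)
    b <- betaValues(me)
    expect_lt(abs(mean(is.na(b)) - 0.05),
              3 * sqrt(0.05 * 0.95 / length(b)))
    expect_false(anyNA(S4Vectors::metadata(me)$beta_complete))
})
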
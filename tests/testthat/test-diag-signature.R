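test_that("balanced accuracy is the mean of sensitivity and specificity", {
    expect_equal(balancedAccuracy(10, 0, 5, 0), 1.0)
    expect_equal(balancedAccuracy(0, 10, 0, 5), 0.0)
    expect_equal(balancedAccuracy(8, 2, 9, 1), 0.85)
    expect_error(balancedAccuracy(0, 0, 5, 0), "positive class")
    expect_error(balancedAccuracy(3, 1, 0, 0), "negative class")
})

test_that("the optimal threshold separates separable markers in both directions", {
    g <- rep(c("tumor", "normal"), each = 3)
    hi <- optimalThreshold(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1), g)
    expect_equal(hi$ba, 1.0)
    expect_equal(hi$direction, "hyper")
    expect_true(hi$threshold > 0.1 && hi$threshold < 0.9)
    lo <- optimalThreshold(c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85), g)
    expect_equal(lo$ba, 1.0)
    expect_equal(lo$direction, "hypo")
    expect_warning(cst <- optimalThreshold(rep(0.4, 6), g), "constant")
    expect_equal(cst$ba, 0.5)
    expect_true(cst$constant)
})

test_that("the threshold scan matches exhaustive brute force on random instances", {
    set.seed(101)
    for (i in 1:100) {
        n <- sample(6:25, 1)
        x <- runif(n)
        if (i %% 3 == 0) x <- round(x, 1)  # induce ties
        g <- sample(rep(c("tumor", "normal"), c(ceiling(n / 2),
                                                floor(n / 2))))
        if (length(unique(x)) == 1) next
        res <- optimalThreshold(x, g)
        expect_equal(res$ba, brute_force_ba(x, g))
        # the returned rule achieves the returned BA when applied directly
        call_t <- if (res$direction == "hyper") x >= res$threshold
                  else x <= res$threshold
        is_t <- g == "tumor"
        ba <- (sum(call_t & is_t) / sum(is_t) +
               sum(!call_t & !is_t) / sum(!is_t)) / 2
        expect_equal(ba, res$ba)
    }
})

test_that("marker ranking is by BA then FDR then id, conserving the set", {
    cand <- data.frame(marker_id = c("cgC", "cgA", "cgB", "cgD"),
                       ba = c(0.9, 0.95, 0.8, 0.9),
                       fdr = c(1e-3, 1e-3, 1e-3, 1e-8))
    out <- rankMarkers(cand)
    expect_equal(out$marker_id, c("cgA", "cgD", "cgC", "cgB"))
    expect_setequal(out$marker_id, cand$marker_id)
    expect_error(rankMarkers(cand[0, ]), "no candidate")
})

test_that("class-scores are signed cumulative beta sums", {
    b <- tiny_beta(c(0.8, 0.3), 2, 1)
    mk <- data.frame(marker_id = c("cg001", "cg002"),
                     direction = c("hyper", "hypo"))
    expect_equal(unname(classScores(b, mk, k = 1)), 0.8)
    expect_equal(unname(classScores(b, mk, k = 2)), 0.5)
    expect_equal(unname(classScores(b * 0, mk, k = 2)), 0)
    expect_error(classScores(b, data.frame(marker_id = "cgX",
                                           direction = "hyper"), 1), "cgX")
    # linearity: score(k) - score(k-1) = signed beta of the k-th marker
    set.seed(6)
    b2 <- tiny_beta(runif(50), 10, 5)
    mk2 <- data.frame(marker_id = rownames(b2),
                      direction = sample(c("hyper", "hypo"), 10, TRUE))
    for (k in 2:10) {
        d <- classScores(b2, mk2, k) - classScores(b2, mk2, k - 1)
        sgn <- if (mk2$direction[k] == "hyper") 1 else -1
        expect_equal(d, sgn * b2[mk2$marker_id[k], ])
    }
})

test_that("the class-score cutoff follows the quartile formula", {
    expect_equal(tumorCutoff(c(1, 2, 3, 4, 5)), -1)
    expect_equal(tumorCutoff(c(0, 10, 20, 30)), -15)
    expect_equal(tumorCutoff(rep(2.5, 6)), 2.5)
    expect_error(tumorCutoff(c(1, 2, 3)), "at least 4")
})

test_that("perfectly separating markers give mean BA 1 and the smallest k", {
    set.seed(55)
    b <- rbind(matrix(rep(c(0.9, 0.1), c(30, 10)), 5, 40, byrow = TRUE),
               matrix(runif(200), 5, 40))
    dimnames(b) <- list(sprintf("cg%03d", 1:10), sprintf("s%03d", 1:40))
    g <- rep(c("tumor", "normal"), c(30, 10))
    ranked <- data.frame(marker_id = rownames(b),
                         direction = "hyper",
                         ba = c(rep(1, 5), rep(0.6, 5)))
    sel <- selectSignatureSize(b, ranked, nSim = 20, seed = 2, groups = g)
    expect_equal(unname(sel$mean_ba[1:5]), rep(1, 5))
    expect_equal(sel$k_star, 1)  # ties resolve to the most parsimonious k
})

test_that("signature size selection separates planted panels and is seeded", {
    co <- small_cohort()
    me <- co$methylation
    st <- computeMarkerStats(me)
    ranked <- rankDiagnosticCandidates(
        me, st, preselectDiagnosticCandidates(st)$marker_ids)
    sel <- selectSignatureSize(me, ranked, nSim = 25, seed = 5)
    expect_gte(sel$mean_ba[1], 0.97)   # one planted marker near-separates
    expect_lte(sel$k_star, 5)
    sel2 <- selectSignatureSize(me, ranked, nSim = 25, seed = 5)
    expect_identical(sel$mean_ba, sel2$mean_ba)
    expect_identical(sel$k_star, sel2$k_star)
    # invariant to sample order
    perm <- sample(ncol(me))
    sel3 <- selectSignatureSize(betaValues(me)[, perm], ranked, nSim = 25,
                                seed = 5, groups = sampleGroups(me)[perm])
    expect_equal(sel3$mean_ba, sel$mean_ba, tolerance = 0.1)
    expect_error(selectSignatureSize(me, ranked, nSim = 5,
                                     subsample = c(1000, 10)), "exceed")
})

test_that("a fitted signature classifies its training tumors with high sensitivity", {
    co <- small_cohort()
    me <- co$methylation
    st <- computeMarkerStats(me)
    ranked <- rankDiagnosticCandidates(
        me, st, preselectDiagnosticCandidates(st)$marker_ids)
    sig <- fitDiagnostic(me, ranked, k = nrow(ranked))  # boundary: all
    pred <- classifySamples(me, sig)
    g <- sampleGroups(me)
    ev <- evaluateDiagnostic(pred, g)
    expect_gte(ev$sensitivity, 0.75)  # MT sits below Q1 by construction
    # reversing directions violates the orientation assumption
    flipped <- ranked
    flipped$direction <- ifelse(ranked$direction == "hyper", "hypo",
                                "hyper")
    expect_error(fitDiagnostic(me, flipped, k = nrow(flipped)),
                 "directions")
})

test_that("classification at the cutoff boundary is tumor", {
    b <- tiny_beta(c(0.5, 0.5 - 1e-9, 0.8), 1, 3)
    mk <- data.frame(marker_id = "cg001", direction = "hyper",
                     ba = 1, threshold = 0.4)
    sig <- new("DiagnosticSignature", markers = mk, k = 1L, cutoff = 0.5,
               training = list())
    expect_equal(unname(classifySamples(b, sig)),
                 c("tumor", "normal", "tumor"))
})

test_that("signature JSON round-trip reproduces classifications exactly", {
    co <- small_cohort()
    me <- co$methylation
    st <- computeMarkerStats(me)
    ranked <- rankDiagnosticCandidates(
        me, st, preselectDiagnosticCandidates(st)$marker_ids)
    sig <- fitDiagnostic(me, ranked, k = min(3, nrow(ranked)))
    path <- tempfile(fileext = ".json")
    writeSignature(sig, path)
    sig2 <- readSignature(path)
    expect_equal(sig2@cutoff, sig@cutoff)
    expect_identical(classifySamples(me, sig2), classifySamples(me, sig))
})

test_that("ROC AUC equals the Mann-Whitney statistic on random instances", {
    set.seed(77)
    for (i in 1:20) {
        n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
        sc <- c(rnorm(n1, 1), rnorm(n0))
        if (i %% 4 == 0) sc <- round(sc)  # ties
        pos <- rep(c(TRUE, FALSE), c(n1, n0))
        u <- unname(wilcox.test(sc[pos], sc[!pos],
                                exact = FALSE)$statistic)
        expect_equal(rocAUC(sc, pos), u / (n1 * n0))
    }
})

test_that("diagnostic evaluation handles perfect and degenerate cases", {
    pred <- c("tumor", "tumor", "normal", "normal")
    truth <- c("tumor", "tumor", "normal", "normal")
    ev <- evaluateDiagnostic(pred, truth, scores = c(3, 2, 1, 0))
    expect_equal(ev$sensitivity, 1)
    expect_equal(ev$specificity, 1)
    expect_equal(ev$auc, 1)
    ev2 <- evaluateDiagnostic(pred, rep("tumor", 4), scores = c(3, 2, 1, 0))
    expect_false(ev2$auc_defined)
    expect_true(is.na(ev2$auc))
})
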
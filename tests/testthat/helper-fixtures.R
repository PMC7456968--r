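# Shared fixture builders. Everything is generated in code at test time.

# A tiny beta matrix with named markers/samples and explicit group labels.
tiny_beta <- function(values, n_markers, n_samples) {
    matrix(values, n_markers, n_samples,
           dimnames = list(sprintf("cg%03d", seq_len(n_markers)),
                           sprintf("s%03d", seq_len(n_samples))))
}

# Beta matrix whose groups have exact means (constant within group):
# one row per element of ave_t / ave_n.
constant_group_beta <- function(ave_t, ave_n, n_t = 3, n_n = 3) {
    b <- cbind(matrix(rep(ave_t, n_t), ncol = n_t),
               matrix(rep(ave_n, n_n), ncol = n_n))
    dimnames(b) <- list(sprintf("cg%03d", seq_along(ave_t)),
                        c(sprintf("T%02d", seq_len(n_t)),
                          sprintf("N%02d", seq_len(n_n))))
    list(beta = b, groups = rep(c("tumor", "normal"), c(n_t, n_n)))
}

# Small survival data.frame aligned to sample ids.
surv_df <- function(ids, time, status) {
    data.frame(sample_id = ids, os_time = time, os_status = status,
               stringsAsFactors = FALSE)
}

# Default small simulated cohort reused across tests (seeded, cached per
# session).
small_cohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateCohort(cohortConfig(
                n_tumor = 60, n_normal = 20, n_markers = 300,
                n_genes = 100, missing_rate = 0, seed = 11))
        cache
    }
})

# Brute-force single-marker threshold scan: every observed value as a
# threshold, both orientations, confusion table evaluated directly.
brute_force_ba <- function(beta_row, groups) {
    is_t <- groups == "tumor"
    best <- 0
    for (t in unique(beta_row)) {
        for (orient in c("high", "low")) {
            call_t <- if (orient == "high") beta_row >= t else beta_row <= t
            tp <- sum(call_t & is_t); fn <- sum(!call_t & is_t)
            tn <- sum(!call_t & !is_t); fp <- sum(call_t & !is_t)
            ba <- (tp / (tp + fn) + tn / (tn + fp)) / 2
            best <- max(best, ba)
        }
    }
    best
}
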
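# Internal helpers shared across modules.

# Run code under a local, restored RNG state. Derived stage seeds stay
# below 2^31 - 1.
.with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

.derive_seed <- function(seed, offset) {
    (as.numeric(seed) * 1000 + offset) %% 2147483647
}

# Quartiles by linear interpolation between order statistics (stats::quantile
# type 7), the convention used for the class-score cutoff and medians.
.quartiles <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7,
                                          names = FALSE)

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 &&
    x == as.integer(x)

.is_frac <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# Beta-distribution shape parameters from a mean/sd pair (method of
# moments). Requires sd^2 < mu (1 - mu).
.beta_shapes <- function(mu, sd) {
    v <- sd^2
    if (any(v >= mu * (1 - mu)))
        stop("beta method-of-moments needs sd^2 < mean*(1-mean)")
    nu <- mu * (1 - mu) / v - 1
    list(a = mu * nu, b = (1 - mu) * nu)
}
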
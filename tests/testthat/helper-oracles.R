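# Independent oracles used to pin down the differential-methylation stage.

# Brute-force one-way ANOVA by explicit sums of squares (no matrix tricks,
# no shared code with the package internals).
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  cls <- sort(unique(groups))
  k <- length(cls)
  N <- length(values)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (cl in cls) {
    v <- values[groups == cl]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    for (x in v) ssw <- ssw + (x - mean(v))^2
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Studentized-range upper tail by direct numerical integration:
# P(Q > q) with k groups and df degrees of freedom, marginalising the
# pooled-SD scale over its chi distribution. Independent of stats::ptukey.
oracle_tukey_p <- function(q, k, df) {
  prange <- function(x) {
    if (x <= 0) return(0)
    k * stats::integrate(function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  cdf <- stats::integrate(function(s) {
    vapply(s, function(si) {
      2 * df * si * stats::dchisq(df * si^2, df) * prange(q * si)
    }, numeric(1))
  }, 0, Inf, rel.tol = 1e-9)$value
  1 - cdf
}

# Random small multi-group instance for oracle-equivalence checks.
random_anova_instance <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(2:4, 1)
    n_per <- sample(3:8, k, replace = TRUE)
    groups <- rep(paste0("g", seq_len(k)), times = n_per)
    values <- runif(sum(n_per))
    list(values = values, groups = groups, k = k, n = sum(n_per))
  })
}
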
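# Shared fixtures and independent oracles used across the test files.

# The four study noise parameterizations.
study_noise_specs <- function() {
  list(
    gaussian = noise_spec("gaussian", mu = 0, sigma = 3),
    uniform  = noise_spec("uniform", a = -1, b = 1),
    poisson  = noise_spec("poisson", lambda = 10),
    gamma    = noise_spec("gamma", shape = 3, scale = 2)
  )
}

# Brute-force KS statistic: maximize |ECDF - F| over both one-sided ECDF
# limits at every sample point (continuous reference).
oracle_ks <- function(sample, cdf) {
  s <- sort(sample)
  n <- length(s)
  u <- cdf(s)
  max(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u))
}

# Hand-summed Pearson statistic on a fixed binning.
oracle_chi2 <- function(observed, expected) {
  sum((observed - expected)^2 / expected)
}

# Closed-form normal-equations solution for the 9-term polynomial surface.
oracle_polynomial_fit <- function(data) {
  X <- with(data, cbind(1, x, x^2, y, y^2, y^3, x * y, x^2 * y, x * y^2))
  unname(drop(solve(crossprod(X), crossprod(X, data$z))))
}
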
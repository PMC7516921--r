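#' Goodness-of-fit discrepancies between residuals and a noise distribution
#'
#' Each function compares a sample (typically model residuals) against a
#' fully specified reference distribution and reports both the raw test
#' statistic and a nonnegative, scale-free discrepancy -- the "Z score" that
#' enters the upgraded selection criteria. The Z score is defined so that it
#' tends to zero as the sample size grows when the sample really is drawn
#' from the reference:
#'
#' * Kolmogorov--Smirnov: Z = D_n, the sup-distance between the empirical
#'   distribution function and the reference CDF;
#' * Anderson--Darling: Z = A^2 / n;
#' * Pearson chi-squared: Z = chi^2 / n.
#'
#' Under a wrong reference all three stay bounded away from zero, so the
#' `(1 + Z^2)` factor in [gf_criterion()] penalizes models whose residuals
#' do not look like the noise. Setting `zscore_mode = "pvalue"` instead
#' reports Z = max(0, qnorm(1 - p)) from the test's (asymptotic) p-value,
#' for sensitivity analysis; this variant grows with n under a fixed
#' alternative rather than converging to a constant.
#'
#' For a discrete reference (Poisson) the KS sup is taken over the union of
#' sample values and integer support atoms, evaluating both one-sided
#' limits of the ECDF and the reference CDF; Anderson--Darling applies the
#' usual CDF-transform formula with ties kept in sorted order; chi-squared
#' bins on the integer support directly.
#'
#' @param sample Non-empty numeric vector.
#' @param ref A [noise_spec()]: the reference (noise) distribution.
#' @param n_bins Optional number of equiprobable bins for the chi-squared
#'   test before tail merging (continuous references only). Default
#'   `max(2, ceiling(2 * n^(2/5)))`.
#' @param zscore_mode `"statistic"` (default) or `"pvalue"`; see Details.
#' @return An object of class `gof_result`: a list with elements `test`,
#'   `statistic`, `z_score`, `n` and (chi-squared only) `df`.
#' @examples
#' ref <- noise_spec("uniform", a = 0, b = 1)
#' ks_discrepancy(c(0.25, 0.75), ref)$statistic  # 0.25
#' @name gof_discrepancies
NULL

new_gof_result <- function(test, statistic, z_score, n, df = NULL) {
  structure(
    list(test = test, statistic = statistic, z_score = z_score, n = n, df = df),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat("<gof_result> ", x$test, ": statistic = ", format(x$statistic),
      ", Z = ", format(x$z_score), ", n = ", x$n,
      if (!is.null(x$df)) paste0(", df = ", x$df), "\n", sep = "")
  invisible(x)
}

check_gof_sample <- function(sample) {
  if (length(sample) == 0) stop("`sample` must be non-empty", call. = FALSE)
  if (!all(is.finite(sample))) stop("`sample` must be finite", call. = FALSE)
}

#' @rdname gof_discrepancies
#' @export
ks_discrepancy <- function(sample, ref, zscore_mode = c("statistic", "pvalue")) {
  check_gof_sample(sample)
  zscore_mode <- match.arg(zscore_mode)
  n <- length(sample)
  if (ref$discrete) {
    # Both the ECDF and the reference CDF are step functions; the sup over
    # the real line is attained at one of their jump points, approached
    # from either side.
    pts <- sort(unique(c(sample, noise_support_atoms(ref, sample))))
    F_right <- noise_cdf(ref, pts)
    F_left <- noise_cdf(ref, pts - 1e-9)
    E_right <- vapply(pts, function(t) mean(sample <= t), numeric(1))
    E_left <- vapply(pts, function(t) mean(sample < t), numeric(1))
    D <- max(abs(E_right - F_right), abs(E_left - F_left))
  } else {
    u <- noise_cdf(ref, sort(sample))
    i <- seq_len(n)
    D <- max(i / n - u, u - (i - 1) / n)
  }
  z <- if (zscore_mode == "statistic") D else pvalue_z(ks_pvalue(D, n))
  new_gof_result("ks", D, z, n)
}

# Asymptotic Kolmogorov tail probability P(sqrt(n) D > x).
ks_pvalue <- function(D, n) {
  x <- sqrt(n) * D
  if (x < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))
  min(max(p, 0), 1)
}

#' @rdname gof_discrepancies
#' @export
ad_discrepancy <- function(sample, ref, zscore_mode = c("statistic", "pvalue")) {
  check_gof_sample(sample)
  zscore_mode <- match.arg(zscore_mode)
  n <- length(sample)
  u <- noise_cdf(ref, sort(sample))
  n_clip <- sum(u <= 0 | u >= 1)
  if (n_clip == n) {
    stop("degenerate sample: all reference CDF values are 0 or 1", call. = FALSE)
  }
  if (n_clip > 0) {
    message(n_clip, " CDF value(s) at the support boundary were clipped")
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  z <- if (zscore_mode == "statistic") A2 / n else pvalue_z(ad_pvalue(A2))
  new_gof_result("anderson_darling", A2, max(z, 0), n)
}

# Asymptotic p-value for A^2 with a fully specified reference
# (case-0 piecewise approximation).
ad_pvalue <- function(A2) {
  if (A2 < 0.2) {
    1 - exp(-13.436 + 101.14 * A2 - 223.73 * A2^2)
  } else if (A2 < 0.34) {
    1 - exp(-8.318 + 42.796 * A2 - 59.938 * A2^2)
  } else if (A2 < 0.6) {
    exp(0.9177 - 4.279 * A2 - 1.38 * A2^2)
  } else {
    exp(1.2937 - 5.709 * A2 + 0.0186 * A2^2)
  }
}

pvalue_z <- function(p) {
  p <- min(max(p, .Machine$double.xmin), 1)
  max(0, stats::qnorm(1 - p))
}

#' @rdname gof_discrepancies
#' @export
chi2_discrepancy <- function(sample, ref, n_bins = NULL,
                             zscore_mode = c("statistic", "pvalue")) {
  check_gof_sample(sample)
  zscore_mode <- match.arg(zscore_mode)
  n <- length(sample)
  bins <- if (ref$discrete) {
    chi2_bins_discrete(sample, ref, n)
  } else {
    chi2_bins_continuous(sample, ref, n, n_bins)
  }
  if (nrow(bins) < 2 || min(bins$expected) < 5) {
    stop("cannot form >= 2 bins with expected count >= 5", call. = FALSE)
  }
  stat <- sum((bins$observed - bins$expected)^2 / bins$expected)
  df <- nrow(bins) - 1L
  z <- if (zscore_mode == "statistic") {
    stat / n
  } else {
    pvalue_z(stats::pchisq(stat, df, lower.tail = FALSE))
  }
  new_gof_result("chi_squared", stat, z, n, df = df)
}

# Equiprobable bins under the reference, then greedy merging from both
# tails until every expected count is >= 5.
chi2_bins_continuous <- function(sample, ref, n, n_bins) {
  B <- if (is.null(n_bins)) max(2L, ceiling(2 * n^(2 / 5))) else as.integer(n_bins)
  edges <- noise_quantile(ref, seq(0, 1, length.out = B + 1))
  edges[1] <- -Inf
  edges[B + 1] <- Inf
  edges <- unique(edges)
  probs <- diff(noise_cdf(ref, edges))
  observed <- as.numeric(table(cut(sample, edges, right = TRUE)))
  merge_small_bins(observed, n * probs)
}

# Integer-support bins: consecutive integers grouped until each group's
# expected count reaches 5; outermost groups absorb the open tails.
chi2_bins_discrete <- function(sample, ref, n) {
  atoms <- noise_support_atoms(ref, sample)
  probs <- noise_pdf(ref, atoms)
  probs[length(probs)] <- 1 - noise_cdf(ref, max(atoms) - 1)  # upper tail mass
  # Assign each (possibly non-integer) sample value to its nearest atom bin,
  # clamping below 0 into the first bin.
  idx <- pmin(pmax(round(sample), 0), max(atoms)) + 1L
  observed <- tabulate(idx, nbins = length(atoms))
  merge_small_bins(observed, n * probs)
}

# Merge any bin whose expected count falls below 5 into its adjacent
# neighbour (the one with the smaller expected count), starting from the
# most underpopulated bin; with equiprobable or unimodal bin probabilities
# this reduces to merging inward from the tails.
merge_small_bins <- function(observed, expected) {
  while (length(expected) > 2 && min(expected) < 5) {
    i <- which.min(expected)
    j <- if (i == 1) 2L
         else if (i == length(expected)) i - 1L
         else if (expected[i - 1] <= expected[i + 1]) i - 1L
         else i + 1L
    expected[j] <- expected[j] + expected[i]
    observed[j] <- observed[j] + observed[i]
    expected <- expected[-i]
    observed <- observed[-i]
  }
  tibble::tibble(observed = observed, expected = expected)
}

#' Z score of a goodness-of-fit test
#'
#' Dispatch wrapper returning only the `z_score` field of the corresponding
#' discrepancy. `test` accepts the short aliases `"ad"` and `"chi2"`.
#'
#' @inheritParams gof_discrepancies
#' @param test One of `"ks"`, `"anderson_darling"` (alias `"ad"`),
#'   `"chi_squared"` (alias `"chi2"`).
#' @return A single nonnegative number.
#' @examples
#' gof_zscore(rnorm(100, 0, 3), noise_spec("gaussian"), "ks")
#' @export
gof_zscore <- function(sample, ref, test = c("ks", "anderson_darling", "chi_squared"),
                       zscore_mode = c("statistic", "pvalue")) {
  test <- normalize_gof_test(test)
  zscore_mode <- match.arg(zscore_mode)
  res <- switch(test,
    ks = ks_discrepancy(sample, ref, zscore_mode),
    anderson_darling = ad_discrepancy(sample, ref, zscore_mode),
    chi_squared = chi2_discrepancy(sample, ref, zscore_mode = zscore_mode)
  )
  res$z_score
}

normalize_gof_test <- function(test) {
  test <- test[1]
  aliases <- c(ks = "ks", ad = "anderson_darling", anderson_darling = "anderson_darling",
               chi2 = "chi_squared", chi_squared = "chi_squared")
  if (!test %in% names(aliases)) {
    stop("unknown goodness-of-fit test: ", test, call. = FALSE)
  }
  unname(aliases[test])
}

#' @export
tidy.gof_result <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, z_score = x$z_score,
    n = x$n, df = if (is.null(x$df)) NA_integer_ else x$df
  )
}
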
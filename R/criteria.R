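#' Shannon entropy of a binned residual distribution
#'
#' Computes H = -sum(p_i log p_i) in nats over a histogram of the
#' residuals, where p_i is the fraction of residuals in bin i; empty bins
#' contribute nothing. Entropy rewards residual distributions without
#' leftover structure, and enters the upgraded criteria as a divisor. The
#' result is floored at eps = 1/n so a degenerate (single-bin) residual
#' vector cannot zero the divisor; when the floor binds the return value
#' carries the attribute `floored = TRUE`.
#'
#' When comparing candidate models, entropy must be computed on identical
#' bin edges for every candidate (pass `bin_edges` spanning the pooled
#' residual range); [criteria_table()] and the benchmark do this
#' automatically. The default binning uses `max(2, ceiling(sqrt(n)))`
#' equal-width bins over the residual range.
#'
#' @param residuals Non-empty numeric vector of residuals (finite).
#' @param n_bins Optional bin count for equal-width binning.
#' @param bin_edges Optional strictly increasing edge vector covering all
#'   residuals; overrides `n_bins`.
#' @return Entropy in nats (a single number), capped at `log(n_bins)`.
#' @examples
#' residual_entropy(c(1, 1, 2, 2), bin_edges = c(0.5, 1.5, 2.5))  # log(2)
#' @export
residual_entropy <- function(residuals, n_bins = NULL, bin_edges = NULL) {
  if (length(residuals) == 0) stop("`residuals` must be non-empty", call. = FALSE)
  if (!all(is.finite(residuals))) stop("`residuals` must be finite", call. = FALSE)
  n <- length(residuals)
  if (is.null(bin_edges)) {
    B <- if (is.null(n_bins)) max(2L, ceiling(sqrt(n))) else as.integer(n_bins)
    lo <- min(residuals)
    hi <- max(residuals)
    if (hi <= lo) {
      # all residuals identical: a single occupied bin, H = 0 before flooring
      return(structure(1 / n, floored = TRUE))
    }
    bin_edges <- seq(lo, hi, length.out = B + 1)
  } else {
    if (any(diff(bin_edges) <= 0)) {
      stop("`bin_edges` must be strictly increasing", call. = FALSE)
    }
    if (min(residuals) < bin_edges[1] || max(residuals) > bin_edges[length(bin_edges)]) {
      stop("`bin_edges` must cover all residuals", call. = FALSE)
    }
  }
  idx <- findInterval(residuals, bin_edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = length(bin_edges) - 1) / n
  H <- -sum(p[p > 0] * log(p[p > 0]))
  if (H < 1 / n) structure(1 / n, floored = TRUE) else H
}

#' Summary statistics of a residual vector
#'
#' Bundles the quantities the selection criteria are built from: the sample
#' size, the mean-squared error (mean of squared residuals), the population
#' (1/n) variance, the binned Shannon entropy, and optionally a
#' goodness-of-fit Z score. With the 1/n convention, `mse = variance +
#' mean(residuals)^2` exactly -- the squared-mean term is what classic
#' criteria wrongly drive to zero under non-zero-mean noise.
#'
#' @inheritParams residual_entropy
#' @param z_score Optional nonnegative goodness-of-fit Z score (see
#'   [gof_zscore()]); required by [gf_criterion()].
#' @return An object of class `residual_summary`: a list with elements `n`,
#'   `mse`, `variance`, `entropy`, `entropy_floored`, `z_score`.
#' @export
residual_summary <- function(residuals, n_bins = NULL, bin_edges = NULL,
                             z_score = NULL) {
  if (length(residuals) == 0) stop("`residuals` must be non-empty", call. = FALSE)
  if (!all(is.finite(residuals))) stop("`residuals` must be finite", call. = FALSE)
  H <- residual_entropy(residuals, n_bins = n_bins, bin_edges = bin_edges)
  structure(
    list(
      n = length(residuals),
      mse = mean(residuals^2),
      variance = mean((residuals - mean(residuals))^2),
      entropy = as.numeric(H),
      entropy_floored = isTRUE(attr(H, "floored")),
      z_score = z_score
    ),
    class = "residual_summary"
  )
}

check_summary <- function(summary, k) {
  stopifnot(is.list(summary))
  if (length(k) != 1 || k < 0 || k != round(k)) {
    stop("`k` must be a nonnegative integer", call. = FALSE)
  }
}

#' Selection criteria from residual summaries
#'
#' The six criteria compared by this package, all cost functions to be
#' minimized over candidate models. With n the sample size, k the model's
#' parameter count, MSE and sigma^2 the mean-squared error and (1/n)
#' variance of its residuals, H their binned Shannon entropy and Z a
#' goodness-of-fit Z score against the known noise distribution:
#'
#' * `classic_criterion()`: AIC = n log(MSE) + 2k; BIC = n log(sigma^2) +
#'   k log(n).
#' * `entropy_criterion()`: AIC_H = n log(MSE / H) + 2k; BIC_H =
#'   n log(sigma^2 / H) + k log(n).
#' * `gf_criterion()`: AIC_GF = n log(MSE (1 + Z^2) / H) + 2k; BIC_GF =
#'   n log(sigma^2 (1 + Z^2) / H) + k log(n).
#' * `gaussian_loglik_criterion()`: the likelihood form -2 log L + penalty
#'   evaluated at the Gaussian maximum-likelihood variance (sigma_hat^2 =
#'   MSE), i.e. AIC = n (log(2 pi MSE) + 1) + 2k. It exceeds the classic
#'   residual form by the model-independent constant n (log(2 pi) + 1).
#'
#' At Z = 0 the GF criteria coincide with the entropy criteria, and at
#' H = 1 the entropy criteria coincide with the classic ones.
#'
#' @param kind `"aic"` or `"bic"`.
#' @param summary A [residual_summary()] (with `z_score` set for
#'   `gf_criterion()`).
#' @param k Number of model parameters (nonnegative integer).
#' @param residuals Numeric residual vector
#'   (`gaussian_loglik_criterion()` only).
#' @return A single number; lower values indicate a preferred model.
#' @examples
#' s <- residual_summary(rnorm(100), z_score = 0.1)
#' classic_criterion("aic", s, k = 3)
#' gf_criterion("bic", s, k = 3)
#' @export
classic_criterion <- function(kind = c("aic", "bic"), summary, k) {
  kind <- match.arg(kind)
  check_summary(summary, k)
  n <- summary$n
  if (kind == "aic") {
    if (summary$mse <= 0) stop("degenerate fit: mse is 0", call. = FALSE)
    n * log(summary$mse) + 2 * k
  } else {
    if (summary$variance <= 0) stop("degenerate fit: variance is 0", call. = FALSE)
    n * log(summary$variance) + k * log(n)
  }
}

#' @rdname classic_criterion
#' @export
entropy_criterion <- function(kind = c("aic", "bic"), summary, k) {
  kind <- match.arg(kind)
  check_summary(summary, k)
  classic_criterion(kind, summary, k) - summary$n * log(summary$entropy)
}

#' @rdname classic_criterion
#' @export
gf_criterion <- function(kind = c("aic", "bic"), summary, k) {
  kind <- match.arg(kind)
  check_summary(summary, k)
  z <- summary$z_score
  if (is.null(z)) stop("`summary` has no z_score; supply one", call. = FALSE)
  if (!is.finite(z) || z < 0) stop("z_score must be a nonnegative number", call. = FALSE)
  entropy_criterion(kind, summary, k) + summary$n * log(1 + z^2)
}

#' @rdname classic_criterion
#' @export
gaussian_loglik_criterion <- function(kind = c("aic", "bic"), residuals, k) {
  kind <- match.arg(kind)
  if (length(residuals) == 0) stop("`residuals` must be non-empty", call. = FALSE)
  n <- length(residuals)
  mse <- mean(residuals^2)
  if (mse <= 0) stop("degenerate fit: mse is 0", call. = FALSE)
  neg2loglik <- n * (log(2 * pi * mse) + 1)
  penalty <- if (kind == "aic") 2 * k else k * log(n)
  neg2loglik + penalty
}

#' All six criteria for one candidate model
#'
#' Computes the residual summary, the goodness-of-fit Z score against the
#' reference noise distribution, and the six criteria, returned as a tidy
#' table with one row per criterion.
#'
#' @inheritParams residual_entropy
#' @param k Number of model parameters.
#' @param ref A [noise_spec()]: the noise distribution the residuals are
#'   tested against.
#' @param gof_test Which discrepancy feeds the GF criteria: `"ks"`,
#'   `"anderson_darling"`/`"ad"` or `"chi_squared"`/`"chi2"`.
#' @param model_label Label carried into the output (e.g. `"Correct"`).
#' @param zscore_mode Passed to [gof_zscore()].
#' @return A tibble with columns `model_label`, `criterion` (aic, bic,
#'   aic_h, bic_h, aic_gf, bic_gf), `value`, `n`, `k`, `mse`, `variance`,
#'   `entropy`, `z_score`, `gof_test`.
#' @examples
#' ref <- noise_spec("gaussian", mu = 0, sigma = 3)
#' criteria_table(noise_sample(ref, 200, seed = 1), k = 2, ref = ref)
#' @export
criteria_table <- function(residuals, k, ref,
                           gof_test = c("ks", "anderson_darling", "chi_squared"),
                           n_bins = NULL, bin_edges = NULL,
                           model_label = "model",
                           zscore_mode = c("statistic", "pvalue")) {
  gof_test <- normalize_gof_test(gof_test)
  zscore_mode <- match.arg(zscore_mode)
  z <- gof_zscore(residuals, ref, gof_test, zscore_mode)
  s <- residual_summary(residuals, n_bins = n_bins, bin_edges = bin_edges,
                        z_score = z)
  values <- c(
    aic = classic_criterion("aic", s, k),
    bic = classic_criterion("bic", s, k),
    aic_h = entropy_criterion("aic", s, k),
    bic_h = entropy_criterion("bic", s, k),
    aic_gf = gf_criterion("aic", s, k),
    bic_gf = gf_criterion("bic", s, k)
  )
  tibble::tibble(
    model_label = model_label,
    criterion = names(values),
    value = unname(values),
    n = s$n, k = as.integer(k),
    mse = s$mse, variance = s$variance, entropy = s$entropy,
    z_score = z, gof_test = gof_test
  )
}
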
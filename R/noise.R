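#' Specify a reference noise distribution
#'
#' A `noise_spec` describes the additive noise assumed to corrupt the data:
#' one of four families with fully specified parameters. It supplies the
#' density/mass, distribution function, analytic mean and seeded sampling
#' used both to generate synthetic data and as the reference distribution
#' for the goodness-of-fit discrepancies.
#'
#' Parameter defaults are the study conditions used throughout the package's
#' benchmark: Gaussian(mu = 0, sigma = 3), Uniform(-1, 1), Poisson(lambda =
#' 10) and Gamma(shape = 3, scale = 2). The gamma family uses the
#' shape--scale parameterization, density x^(k-1) e^(-x/theta) / (theta^k
#' Gamma(k)). The Poisson family is a discrete distribution over the
#' nonnegative integers; `discrete = TRUE` routes the discrete handling in
#' the goodness-of-fit tests.
#'
#' @param family One of `"gaussian"`, `"uniform"`, `"poisson"`, `"gamma"`.
#' @param mu,sigma Gaussian location and scale (`sigma > 0`).
#' @param a,b Uniform bounds (`a < b`).
#' @param lambda Poisson rate (`lambda > 0`).
#' @param shape,scale Gamma shape and scale (both `> 0`).
#' @return An object of class `noise_spec`: a list with elements `family`,
#'   `params` (named list) and `discrete`.
#' @examples
#' noise_spec("poisson", lambda = 10)
#' noise_spec("gamma", shape = 3, scale = 2)
#' @export
noise_spec <- function(family = c("gaussian", "uniform", "poisson", "gamma"),
                       mu = 0, sigma = 3, a = -1, b = 1, lambda = 10,
                       shape = 3, scale = 2) {
  family <- match.arg(family)
  params <- switch(family,
    gaussian = list(mu = mu, sigma = sigma),
    uniform  = list(a = a, b = b),
    poisson  = list(lambda = lambda),
    gamma    = list(shape = shape, scale = scale)
  )
  spec <- structure(
    list(family = family, params = params, discrete = identical(family, "poisson")),
    class = "noise_spec"
  )
  validate_noise_spec(spec)
  spec
}

validate_noise_spec <- function(spec) {
  p <- spec$params
  bad <- switch(spec$family,
    gaussian = !is.finite(p$mu) || !is.finite(p$sigma) || p$sigma <= 0,
    uniform  = !is.finite(p$a) || !is.finite(p$b) || p$a >= p$b,
    poisson  = !is.finite(p$lambda) || p$lambda <= 0,
    gamma    = !is.finite(p$shape) || !is.finite(p$scale) || p$shape <= 0 || p$scale <= 0
  )
  if (bad) {
    stop("invalid parameters for ", spec$family, " noise: ",
         paste(names(p), unlist(p), sep = " = ", collapse = ", "),
         call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> ", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Density, distribution function, quantiles and mean of a noise spec
#'
#' `noise_pdf()` evaluates the density (probability mass for the discrete
#' Poisson family; zero off the integer support), `noise_cdf()` the
#' cumulative distribution function, `noise_quantile()` its inverse, and
#' `noise_mean()` the analytic mean (mu; (a+b)/2; lambda; shape * scale).
#'
#' @param spec A [noise_spec()].
#' @param x Numeric vector of evaluation points.
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return A numeric vector (`noise_mean()` returns a single number).
#' @examples
#' ref <- noise_spec("gaussian", mu = 0, sigma = 3)
#' noise_pdf(ref, 0)
#' noise_cdf(ref, 0)
#' noise_mean(noise_spec("gamma", shape = 3, scale = 2))
#' @export
noise_pdf <- function(spec, x) {
  stopifnot(inherits(spec, "noise_spec"))
  p <- spec$params
  switch(spec$family,
    gaussian = stats::dnorm(x, p$mu, p$sigma),
    uniform  = stats::dunif(x, p$a, p$b),
    poisson  = ifelse(x >= 0 & abs(x - round(x)) < 1e-8,
                      stats::dpois(round(x), p$lambda), 0),
    gamma    = stats::dgamma(x, shape = p$shape, scale = p$scale)
  )
}

#' @rdname noise_pdf
#' @export
noise_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "noise_spec"))
  p <- spec$params
  switch(spec$family,
    gaussian = stats::pnorm(x, p$mu, p$sigma),
    uniform  = stats::punif(x, p$a, p$b),
    poisson  = stats::ppois(floor(x), p$lambda),
    gamma    = stats::pgamma(x, shape = p$shape, scale = p$scale)
  )
}

#' @rdname noise_pdf
#' @export
noise_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "noise_spec"))
  pr <- spec$params
  switch(spec$family,
    gaussian = stats::qnorm(p, pr$mu, pr$sigma),
    uniform  = stats::qunif(p, pr$a, pr$b),
    poisson  = stats::qpois(p, pr$lambda),
    gamma    = stats::qgamma(p, shape = pr$shape, scale = pr$scale)
  )
}

#' @rdname noise_pdf
#' @export
noise_mean <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  p <- spec$params
  switch(spec$family,
    gaussian = p$mu,
    uniform  = (p$a + p$b) / 2,
    poisson  = p$lambda,
    gamma    = p$shape * p$scale
  )
}

# Draw from the current RNG stream (no seed handling). Used internally so a
# single seed can govern a whole dataset (covariates + noise) reproducibly.
noise_draw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    gaussian = stats::rnorm(n, p$mu, p$sigma),
    uniform  = stats::runif(n, p$a, p$b),
    poisson  = as.numeric(stats::rpois(n, p$lambda)),
    gamma    = stats::rgamma(n, shape = p$shape, scale = p$scale)
  )
}

#' Draw a seeded i.i.d. sample from a noise spec
#'
#' Sampling is isolated from the global RNG state: the same `(spec, n,
#' seed)` always reproduces the same draws and the caller's random state is
#' left untouched.
#'
#' @param spec A [noise_spec()].
#' @param n Number of draws (`n >= 1`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' identical(noise_sample(noise_spec("poisson"), 5, seed = 42),
#'           noise_sample(noise_spec("poisson"), 5, seed = 42))
#' @export
noise_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "noise_spec"))
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), noise_draw(spec, n))
}

# Integer support atoms covering all but ~1e-12 of a discrete spec's mass,
# extended to cover the sample range when needed.
noise_support_atoms <- function(spec, sample = numeric(0)) {
  stopifnot(spec$discrete)
  hi <- stats::qpois(1 - 1e-12, spec$params$lambda)
  if (length(sample)) hi <- max(hi, ceiling(max(sample)))
  0:hi
}

#' Serialize a noise spec to/from JSON
#'
#' The JSON form `{"family": ..., "params": {...}}` is used in benchmark
#' configuration files and on the command line.
#'
#' @param spec A [noise_spec()].
#' @param json A JSON string or a list with elements `family` and `params`.
#' @return `noise_to_json()` a JSON string; `noise_from_json()` a
#'   [noise_spec()].
#' @export
noise_to_json <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  jsonlite::toJSON(list(family = spec$family, params = spec$params),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname noise_to_json
#' @export
noise_from_json <- function(json) {
  obj <- if (is.character(json)) jsonlite::fromJSON(json) else json
  do.call(noise_spec, c(list(family = obj$family), as.list(obj$params)))
}
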
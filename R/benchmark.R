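#' Generate a synthetic dataset from a model plus additive noise
#'
#' Covariates are drawn i.i.d. uniformly over the rectangular domain, the
#' generating surface is evaluated, and uncentered i.i.d. noise is added.
#' Everything (covariates and noise) is governed by one seed, and the
#' generating model, noise spec and seed are recorded as attributes.
#'
#' The default domain is `0 < x < 10`, `-10 < y < 10`. For the power-law
#' generator, whose negative exponent is singular at `y = 0` (and
#' ill-defined for `y < 0` with non-integer exponents), a `y_range`
#' containing 0 is rejected; the benchmark uses `(0.5, 10)` for that case.
#'
#' @param generator A [model_spec()]: the generating function.
#' @param noise A [noise_spec()]; use `NULL` for noise-free data.
#' @param n Number of points.
#' @param x_range,y_range Length-2 numeric ranges of the covariates.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`, `z` and attributes `generator`,
#'   `noise`, `seed`.
#' @examples
#' d <- generate_dataset(generating_model("exponential"),
#'                       noise_spec("poisson", lambda = 10), n = 200, seed = 1)
#' head(d)
#' @export
generate_dataset <- function(generator, noise, n, x_range = c(0, 10),
                             y_range = c(-10, 10), seed = 1) {
  stopifnot(inherits(generator, "model_spec"), n >= 1)
  if (generator$family == "power_law") {
    b <- generator$parameters[["b"]]
    a <- generator$parameters[["a"]]
    if ((b < 0 || b != round(b)) && (y_range[1] <= 0)) {
      stop("power-law generator with exponent b = ", b,
           " needs a strictly positive y_range (e.g. c(0.5, 10))", call. = FALSE)
    }
    if ((a < 0 || a != round(a)) && (x_range[1] <= 0)) {
      stop("power-law generator with exponent a = ", a,
           " needs a strictly positive x_range", call. = FALSE)
    }
  }
  dat <- withr::with_seed(as.integer(seed), {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- stats::runif(n, y_range[1], y_range[2])
    eps <- if (is.null(noise)) rep(0, n) else noise_draw(noise, n)
    tibble::tibble(x = x, y = y, z = evaluate_model(generator, x, y) + eps)
  })
  attr(dat, "generator") <- generator
  attr(dat, "noise") <- noise
  attr(dat, "seed") <- as.integer(seed)
  dat
}

#' Configure a Correct-vs-Alternative benchmark
#'
#' Bundles everything one simulation protocol needs: the benchmark case
#' (which generating function and which fit family plays the Alternative),
#' the noise distribution, the covariate domain, the sample-size grid, the
#' number of repetitions, the goodness-of-fit test feeding the GF criteria,
#' and the master seed from which all per-repetition seeds derive.
#'
#' By default each case's Alternative is the matching fit family
#' (exponential case fits the 7-parameter exponential family, polynomial
#' case the 9-term polynomial, power-law case the 3-parameter power law).
#' For the power-law case the default `y_range` is `(0.5, 10)` to keep the
#' generator finite.
#'
#' @param case `"exponential"`, `"polynomial"` or `"power_law"`.
#' @param noise A [noise_spec()] (default Poisson(lambda = 10)).
#' @param alternative_family Fit family of the Alternative model; defaults
#'   to the case's own family.
#' @param x_range,y_range Covariate domain.
#' @param n_grid Strictly increasing sample sizes for [scan_sample_size()].
#' @param n Fixed sample size for [scan_noise_intensity()].
#' @param reps Repetitions averaged per grid point.
#' @param gof_test Discrepancy feeding the GF criteria (`"ks"`, `"ad"`,
#'   `"chi2"`).
#' @param seed Master seed.
#' @param intensity_grid Noise-parameter grid for [scan_noise_intensity()]
#'   (sigma for Gaussian, lambda for Poisson).
#' @param correct_k Complexity charged to the Correct model; default: the
#'   generating function's printed-constant count (see
#'   [generating_model()]).
#' @param refit_correct If `TRUE`, the Correct candidate is the generating
#'   family refit to the data instead of the true-parameter function
#'   (sensitivity analysis; default `FALSE`).
#' @param zscore_mode Passed to [gof_zscore()].
#' @param power_law_c Scale constant of the power-law generator.
#' @return An object of class `benchmark_config`.
#' @examples
#' cfg <- benchmark_config("exponential", noise_spec("poisson"), reps = 3,
#'                         n_grid = c(100, 500))
#' @export
benchmark_config <- function(case = c("exponential", "polynomial", "power_law"),
                             noise = noise_spec("poisson", lambda = 10),
                             alternative_family = NULL,
                             x_range = c(0, 10), y_range = NULL,
                             n_grid = c(50, 100, 200, 500, 1000, 2000),
                             n = 1000, reps = 10,
                             gof_test = c("ks", "anderson_darling", "chi_squared"),
                             seed = 1, intensity_grid = NULL,
                             correct_k = NULL, refit_correct = FALSE,
                             zscore_mode = c("statistic", "pvalue"),
                             power_law_c = 1) {
  case <- match.arg(case)
  gof_test <- normalize_gof_test(gof_test)
  zscore_mode <- match.arg(zscore_mode)
  stopifnot(inherits(noise, "noise_spec"), reps >= 1)
  if (is.null(y_range)) {
    y_range <- if (case == "power_law") c(0.5, 10) else c(-10, 10)
  }
  if (any(diff(n_grid) <= 0)) stop("`n_grid` must be strictly increasing", call. = FALSE)
  structure(
    list(
      case = case, noise = noise,
      alternative_family = alternative_family %||% case,
      x_range = x_range, y_range = y_range,
      n_grid = n_grid, n = n, reps = reps, gof_test = gof_test,
      seed = as.integer(seed), intensity_grid = intensity_grid,
      correct_k = correct_k, refit_correct = refit_correct,
      zscore_mode = zscore_mode, power_law_c = power_law_c
    ),
    class = "benchmark_config"
  )
}

#' Compare the Correct and Alternative models on one simulated dataset
#'
#' Generates one dataset under the configured noise, computes the Correct
#' model's residuals (which reproduce the drawn noise vector exactly, by
#' additive cancellation), fits the Alternative family by least squares,
#' and evaluates all six criteria for both candidates. Entropy is computed
#' on shared bin edges spanning the pooled residual range of both models so
#' the criteria are comparable.
#'
#' @param config A [benchmark_config()].
#' @param n Sample size for this comparison.
#' @param rep_seed Integer seed for this repetition.
#' @param noise Optional [noise_spec()] overriding `config$noise` (used by
#'   the intensity scan).
#' @return A tibble: two models x six criteria rows, in the
#'   [criteria_table()] schema plus a `converged` column.
#' @examples
#' cfg <- benchmark_config("power_law", noise_spec("poisson"))
#' run_comparison(cfg, n = 200, rep_seed = 11)
#' @export
run_comparison <- function(config, n, rep_seed, noise = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  noise <- noise %||% config$noise
  gen <- generating_model(config$case, c = config$power_law_c, k = config$correct_k)
  dat <- generate_dataset(gen, noise, n, config$x_range, config$y_range,
                          seed = rep_seed)

  if (isTRUE(config$refit_correct) && gen$family != "custom") {
    correct_fit <- fit_model(dat, gen$family, init = gen$parameters,
                             label = "Correct")
    res_correct <- compute_residuals(dat, correct_fit)
    correct_k <- correct_fit$model$k
    correct_conv <- correct_fit$converged
  } else {
    res_correct <- compute_residuals(dat, gen)
    correct_k <- gen$k
    correct_conv <- TRUE
  }

  fit <- fit_model(dat, config$alternative_family)
  res_alt <- compute_residuals(dat, fit)

  # Entropy uses the same bin COUNT for both candidates but each model's own
  # residual range: H is then a scale-invariant measure of the shape of the
  # residual distribution (its uniformity), not of its spread. Binning both
  # models over the pooled range would reward the worse model simply for
  # having wider residuals.
  B <- max(2L, ceiling(sqrt(n)))

  dplyr::bind_rows(
    dplyr::mutate(
      criteria_table(res_correct, k = correct_k, ref = noise,
                     gof_test = config$gof_test, n_bins = B,
                     model_label = "Correct",
                     zscore_mode = config$zscore_mode),
      converged = correct_conv
    ),
    dplyr::mutate(
      criteria_table(res_alt, k = fit$model$k, ref = noise,
                     gof_test = config$gof_test, n_bins = B,
                     model_label = "Alternative",
                     zscore_mode = config$zscore_mode),
      converged = fit$converged
    )
  )
}

# One sub-seed per repetition x grid point, derived reproducibly from the
# master seed; kept below 2^31.
derive_seeds <- function(master, count) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max - 1, count))
}

#' Scan sample size (or noise intensity) and average over repetitions
#'
#' `scan_sample_size()` runs [run_comparison()] at every `n` in
#' `config$n_grid` for `config$reps` seeded repetitions.
#' `scan_noise_intensity()` instead holds `n = config$n` fixed and varies
#' the noise parameter (the standard deviation for Gaussian noise, lambda
#' for Poisson) over `config$intensity_grid`. Both return every individual
#' criterion value; use [scan_summary()] for per-point means and standard
#' deviations and [selection_rates()] for how often each criterion prefers
#' the Correct model. Identical configs (including the master seed) yield
#' identical results.
#'
#' @param config A [benchmark_config()].
#' @return A tibble of class `gof_scan` with columns `n_or_intensity`,
#'   `rep`, `model_label`, `criterion`, `value`, `n`, `k`, `mse`,
#'   `variance`, `entropy`, `z_score`, `gof_test`, `converged`, and
#'   attributes `scan_kind` (`"n"` or `"intensity"`) and `config`.
#' @examples
#' cfg <- benchmark_config("power_law", noise_spec("gaussian"),
#'                         n_grid = c(50, 100), reps = 2)
#' scan_summary(scan_sample_size(cfg))
#' @export
scan_sample_size <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  grid <- config$n_grid
  if (length(grid) == 0) stop("`n_grid` is empty", call. = FALSE)
  seeds <- matrix(derive_seeds(config$seed, length(grid) * config$reps),
                  nrow = length(grid))
  rows <- purrr::map_dfr(seq_along(grid), function(i) {
    purrr::map_dfr(seq_len(config$reps), function(r) {
      dplyr::mutate(
        run_comparison(config, n = grid[i], rep_seed = seeds[i, r]),
        n_or_intensity = grid[i], rep = r, .before = 1
      )
    })
  })
  as_gof_scan(rows, "n", config)
}

#' @rdname scan_sample_size
#' @export
scan_noise_intensity <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  grid <- config$intensity_grid
  if (is.null(grid) || length(grid) == 0) {
    stop("`intensity_grid` is empty", call. = FALSE)
  }
  if (!config$noise$family %in% c("gaussian", "poisson")) {
    stop("intensity scans support gaussian (sigma) and poisson (lambda) noise",
         call. = FALSE)
  }
  seeds <- matrix(derive_seeds(config$seed, length(grid) * config$reps),
                  nrow = length(grid))
  rows <- purrr::map_dfr(seq_along(grid), function(i) {
    noise_i <- if (config$noise$family == "gaussian") {
      noise_spec("gaussian", mu = config$noise$params$mu, sigma = grid[i])
    } else {
      noise_spec("poisson", lambda = grid[i])
    }
    purrr::map_dfr(seq_len(config$reps), function(r) {
      dplyr::mutate(
        run_comparison(config, n = config$n, rep_seed = seeds[i, r],
                       noise = noise_i),
        n_or_intensity = grid[i], rep = r, .before = 1
      )
    })
  })
  as_gof_scan(rows, "intensity", config)
}

as_gof_scan <- function(rows, kind, config) {
  structure(rows,
            class = c("gof_scan", class(rows)),
            scan_kind = kind, config = config)
}

#' Summarize a benchmark scan
#'
#' `scan_summary()` averages criterion values over repetitions (mean and
#' standard deviation per grid point, model and criterion). Repetitions
#' whose fit did not converge are excluded from the averages; the excluded
#' count is reported per group. `selection_rates()` reports, per grid point
#' and criterion, the fraction of repetitions in which each criterion
#' assigns its lowest value to the Correct model.
#'
#' @param scan A `gof_scan` from [scan_sample_size()] or
#'   [scan_noise_intensity()].
#' @return A tibble.
#' @export
scan_summary <- function(scan) {
  scan |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$n_or_intensity, .data$model_label, .data$criterion) |>
    dplyr::summarise(
      mean = mean(.data$value[.data$converged]),
      sd = stats::sd(.data$value[.data$converged]),
      reps = sum(.data$converged),
      excluded = sum(!.data$converged),
      .groups = "drop"
    )
}

#' @rdname scan_summary
#' @export
selection_rates <- function(scan) {
  scan |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$n_or_intensity, .data$rep) |>
    dplyr::filter(all(.data$converged)) |>
    dplyr::group_by(.data$n_or_intensity, .data$rep, .data$criterion) |>
    dplyr::summarise(
      correct_selected =
        .data$model_label[which.min(.data$value)] == "Correct",
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$n_or_intensity, .data$criterion) |>
    dplyr::summarise(
      correct_rate = mean(.data$correct_selected),
      reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Write a scan to CSV
#'
#' Writes the full per-repetition results in a flat schema (`case`,
#' `noise_family`, `noise_params` as JSON, `n_or_intensity`, `rep`,
#' `model_label`, `criterion`, `value`, `mse`, `variance`, `entropy`,
#' `z_score`, `converged`). Output bytes are a pure function of the scan,
#' so identical configs produce identical files.
#'
#' @param scan A `gof_scan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  config <- attr(scan, "config")
  out <- scan |>
    tibble::as_tibble() |>
    dplyr::mutate(
      case = config$case,
      noise_family = config$noise$family,
      noise_params = as.character(noise_to_json(config$noise)),
      .before = 1
    ) |>
    dplyr::select(dplyr::all_of(c(
      "case", "noise_family", "noise_params", "n_or_intensity", "rep",
      "model_label", "criterion", "value", "mse", "variance", "entropy",
      "z_score", "converged"
    )))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects a header `x,y,z`, the on-disk form of [generate_dataset()]
#' output.
#'
#' @param path CSV file path.
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
read_dataset_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y", "z") %in% names(dat))) {
    stop("dataset CSV must have columns x, y, z", call. = FALSE)
  }
  dat
}
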
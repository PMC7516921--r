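#' Plot a benchmark scan
#'
#' Draws the repetition-averaged value of each criterion against the sample
#' size (or noise intensity), one panel per criterion, coloured by
#' candidate model; ribbons show +/- one standard deviation across
#' repetitions. This is the package's analogue of the benchmark figures:
#' where a criterion works, the Correct curve lies below the Alternative
#' one.
#'
#' @param object A `gof_scan` from [scan_sample_size()] or
#'   [scan_noise_intensity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cfg <- benchmark_config("power_law", noise_spec("poisson"),
#'                         n_grid = c(100, 300), reps = 2)
#' autoplot(scan_sample_size(cfg))
#' @export
autoplot.gof_scan <- function(object, ...) {
  kind <- attr(object, "scan_kind")
  xlab <- if (identical(kind, "intensity")) "noise intensity" else "sample size n"
  summ <- scan_summary(object)
  ggplot2::ggplot(
    summ,
    ggplot2::aes(x = .data$n_or_intensity, y = .data$mean,
                 colour = .data$model_label, fill = .data$model_label)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = "criterion value (lower is better)",
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
}

#' Plot a noise distribution
#'
#' Density (or probability mass) curve of a [noise_spec()], handy for
#' checking a configured reference distribution.
#'
#' @param object A [noise_spec()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_spec <- function(object, ...) {
  if (object$discrete) {
    atoms <- noise_support_atoms(object)
    atoms <- atoms[noise_pdf(object, atoms) > 1e-8]
    df <- tibble::tibble(x = atoms, density = noise_pdf(object, atoms))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density)) +
      ggplot2::geom_col(width = 0.1)
  } else {
    lo <- noise_quantile(object, 1e-4)
    hi <- noise_quantile(object, 1 - 1e-4)
    xs <- seq(lo, hi, length.out = 400)
    df <- tibble::tibble(x = xs, density = noise_pdf(object, xs))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density)) +
      ggplot2::geom_line()
  }
  p +
    ggplot2::labs(
      title = paste0(object$family, "(",
                     paste(names(object$params), unlist(object$params),
                           sep = " = ", collapse = ", "), ")"),
      x = "value", y = if (object$discrete) "probability" else "density"
    ) +
    ggplot2::theme_minimal()
}
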
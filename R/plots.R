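#' Plot reflectance spectra
#'
#' @param spectra Spectra tibble.
#' @param samples Optional sample table; when given, curves are coloured by
#'   `colour_by`.
#' @param colour_by Column of `samples` used for colour (default
#'   `treatment`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, samples = NULL, colour_by = "treatment") {
  long <- spc_longer(spectra)
  if (!is.null(samples)) {
    long <- dplyr::left_join(long,
      samples[c("sample_id", colour_by)],
      by = "sample_id"
    )
    p <- ggplot2::ggplot(long, ggplot2::aes(
      .data$wavelength, .data$reflectance,
      group = .data$sample_id, colour = .data[[colour_by]]
    ))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      .data$wavelength, .data$reflectance, group = .data$sample_id
    ))
  }
  p + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
}

#' @describeIn swt_decompose Plot all approximation and detail series of a
#'   decomposition, one panel per (series, level).
#' @param object A `dyadic_swt` object.
#' @param ... Unused.
#' @method autoplot dyadic_swt
#' @export
autoplot.dyadic_swt <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      x = if (all(is.na(.data$wavelength))) .data$band_index else .data$wavelength,
      panel = sprintf("%s%d", .data$series, .data$level)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = object$levels) +
    ggplot2::labs(
      x = if (all(is.na(df$wavelength))) "band index" else "wavelength (nm)",
      y = "coefficient"
    )
}

#' Plot per-band wavelet coefficient correlation curves
#'
#' Displays the screening curves from [coefficient_correlations()]; the
#' selected sensitivity coefficients can be overlaid as points.
#'
#' @param correlations Tibble from [coefficient_correlations()].
#' @param selection Optional tibble from
#'   [select_sensitivity_coefficients()].
#' @return A ggplot object.
#' @export
plot_coefficient_correlations <- function(correlations, selection = NULL) {
  p <- ggplot2::ggplot(correlations, ggplot2::aes(
    .data$wavelength, .data$r, colour = factor(.data$level)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_grid(band_type ~ basis) +
    ggplot2::labs(
      x = "wavelength (nm)", y = "correlation with response",
      colour = "level"
    )
  if (!is.null(selection)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(selection, band_type = "detail"),
      ggplot2::aes(.data$wavelength, .data$r), colour = "black", size = 2
    )
  }
  p
}

#' @method autoplot npk_comparison
#' @export
autoplot.npk_comparison <- function(object, ...) {
  ggplot2::ggplot(object$best, ggplot2::aes(
    .data$model_id, .data$t, fill = .data$model_id
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = NULL, y = "composite score T") +
    ggplot2::guides(fill = "none")
}

#' Plot composite scores of all evaluated models
#'
#' @param evaluation Evaluation tibble from [run_npk_pipeline()] (columns
#'   `response`, `model_id`, `t`).
#' @return A ggplot object; lower bars are better models.
#' @export
plot_model_scores <- function(evaluation) {
  ggplot2::ggplot(evaluation, ggplot2::aes(
    stats::reorder(.data$model_id, .data$t), .data$t
  )) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$type)) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composite score T", fill = "model class")
}
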
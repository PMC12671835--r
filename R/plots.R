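#' Diagnostic plots for FPF fits and model comparisons
#'
#' `autoplot.fpf_fit()` overlays the fitted FPF density on a histogram of
#' the data (`type = "density"`) or the fitted CDF on the empirical CDF
#' (`type = "cdf"`). `autoplot.fpf_comparison()` overlays the fitted
#' densities of every successfully fitted model on the data histogram.
#'
#' @param object An `fpf_fit` or `fpf_comparison` object.
#' @param type Which panel to draw.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fpf_fit <- function(object, type = c("density", "cdf"), bins = 20,
                             ...) {
  type <- match.arg(type)
  x <- object$data
  p <- fpf_params(1, object$lambda, object$bounds[1], object$bounds[2])
  df <- tibble::tibble(x = x)
  grid <- tibble::tibble(
    x = seq(object$bounds[1] + 1e-9 * diff(object$bounds),
            object$bounds[2], length.out = 400)
  )
  if (type == "density") {
    grid$y <- dfpf(grid$x, p, strict = FALSE)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = bins, fill = "grey80",
                              colour = "grey40") +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                         colour = "#2166ac", linewidth = 0.8) +
      ggplot2::labs(x = "x", y = "density",
                    title = "Fitted FPF density",
                    subtitle = sprintf("lambda-hat = %.4g", object$lambda))
  } else {
    grid$y <- pfpf(grid$x, p)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
      ggplot2::stat_ecdf(colour = "grey40") +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                         colour = "#2166ac", linewidth = 0.8) +
      ggplot2::labs(x = "x", y = "F(x)",
                    title = "Empirical vs fitted FPF CDF")
  }
}

#' @rdname autoplot.fpf_fit
#' @exportS3Method ggplot2::autoplot
autoplot.fpf_comparison <- function(object, bins = 20, ...) {
  fits <- attr(object, "fits")
  ok <- purrr::keep(fits, inherits, "fpf_model")
  if (!length(ok)) stop("no successful fits to plot.", call. = FALSE)
  b <- attr(object, "bounds")
  grid_x <- seq(b[1] + 1e-6 * diff(b), b[2] - 1e-6 * diff(b),
                length.out = 400)
  curves <- purrr::imap(ok, function(f, nm) {
    tibble::tibble(x = grid_x, y = f$pdf(grid_x), model = nm)
  }) |> dplyr::bind_rows()
  data_df <- tibble::tibble(x = attr(object, "data"))
  ggplot2::ggplot(data_df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$y, colour = .data$model),
                       linewidth = 0.7) +
    ggplot2::labs(x = "x", y = "density", colour = "model",
                  title = "Fitted candidate densities")
}
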
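#' Plot a fitted effort-bias curve
#'
#' Points, fitted curve, optional confidence band, and the bias = 0 parity
#' reference line (the level at which a checklist matches its site's
#' reference richness).
#'
#' @param object A `power_fit` from [fit_power()].
#' @param band Optional `curve_band` (e.g. [mc_confidence_band()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_fit
#' @export
autoplot.power_fit <- function(object, band = NULL, ...) {
  xr <- if (!is.null(object$data)) range(object$data$x) else c(6, 200)
  grid <- tibble::tibble(x = seq(xr[1], xr[2], length.out = 200))
  grid$y <- predict_bias(object, grid$x)
  p <- ggplot2::ggplot()
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lo95, ymax = .data$hi95),
      fill = "steelblue", alpha = 0.25
    )
  }
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data, ggplot2::aes(.data$x, .data$y),
      shape = 1, alpha = 0.6
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(.data$x, .data$y),
      colour = "blue", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "Duration (min)", y = "Bias",
      subtitle = sprintf(
        "y = %.4f x^%.4f - 1", object$coef, object$exp
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.power_fit
#' @method autoplot curve_band
#' @export
autoplot.curve_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "blue") +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::labs(x = "Duration (min)", y = "Bias") +
    ggplot2::theme_minimal()
}

#' Plot the four effort-bias curves of a pipeline run
#'
#' Faceted version of [autoplot.power_fit()] over the four comparison types
#' (observed/estimated checklist richness vs observed/estimated reference).
#'
#' @param object A `richness_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot richness_run
#' @export
autoplot.richness_run <- function(object, ...) {
  pts <- object$bias_records
  curves <- purrr::imap_dfr(object$fits, function(f, type) {
    x <- seq(min(f$data$x), max(f$data$x), length.out = 200)
    tibble::tibble(bias_type = type, x = x, y = predict_bias(f, x))
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$duration_minutes, .data$bias)) +
    ggplot2::geom_point(shape = 1, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::geom_line(
      data = curves, ggplot2::aes(.data$x, .data$y),
      colour = "blue", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~bias_type) +
    ggplot2::labs(x = "Duration (min)", y = "Bias") +
    ggplot2::theme_minimal()
}
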
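#' Residual change scatter for a mixed-model fit
#'
#' Plots, for each individual with both occasions observed, the
#' fixed-effect residual at baseline against the residual at follow-up,
#' colored by sex. Points on the diagonal show no individual change beyond
#' the fixed effects; mass above (below) the diagonal indicates increase
#' (decrease) over the follow-up.
#'
#' @param x A `twindelta_mixed` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twindelta_mixed
#' @export
autoplot.twindelta_mixed <- function(x, ...) {
  wide <- x$residuals |>
    dplyr::select(dplyr::all_of(c("twin_id", "sex", "time", "residual"))) |>
    tidyr::pivot_wider(names_from = "time", values_from = "residual",
                       names_prefix = "t") |>
    dplyr::filter(!is.na(.data$t1), !is.na(.data$t2))
  ggplot2::ggplot(wide, ggplot2::aes(.data$t1, .data$t2,
                                     colour = factor(.data$sex))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`0` = "black", `1` = "red"),
                                 labels = c(`0` = "male", `1` = "female"),
                                 name = "sex") +
    ggplot2::labs(
      x = "residual, time 1", y = "residual, time 2",
      title = sprintf("Longitudinal trend of %s", x$trait)
    )
}

#' @rdname autoplot.twindelta_mixed
#' @export
plot_change_residuals <- function(x, ...) autoplot.twindelta_mixed(x, ...)

#' Standardized variance components of a selected twin model
#'
#' Bar chart of the best-fitting model's standardized components with
#' bootstrap intervals when available.
#'
#' @param x A `twindelta_selection` from [fit_twin_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twindelta_selection
#' @export
autoplot.twindelta_selection <- function(x, ...) {
  d <- tidy(x$best_fit) |> dplyr::filter(.data$free)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "proportion of variance",
                  title = sprintf("Best model: %s", x$best_model))
  if ("low" %in% names(d) && any(is.finite(d$low))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$low, ymax = .data$high), width = 0.2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
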
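#' Plot marginal curves of a fitted FKMR surface
#'
#' Marginal effect of each (selected, by default) feature over `[0, 1]`
#' with all other features held at 0.5; flat lines correspond to excluded
#' features.
#'
#' @param object An `"fkmr_fit"`.
#' @param features Feature indices to display (default: the selected set).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fkmr_fit <- function(object, features = NULL, ...) {
  if (is.null(features)) features <- object$selected$features
  assert_that(length(features) >= 1L, "no features to plot")
  curves <- purrr::map(features, ~ marginal_curve(object, .x)) |>
    purrr::list_rbind()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$zeta, y = .data$h_hat)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ feature, scales = "free_y") +
    ggplot2::labs(x = expression(zeta), y = expression(hat(h)),
                  title = "Marginal estimates of the fitted surface") +
    ggplot2::theme_minimal()
}

#' Plot selection frequencies of a replicate study
#'
#' Bar panel per method showing the percentage of replicates in which each
#' FPC feature was selected, with the true signals highlighted.
#'
#' @param object An `"fkmr_replicates"`.
#' @param level `"feature"` or `"group"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fkmr_replicates <- function(object, level = c("feature", "group"), ...) {
  level <- match.arg(level)
  freq <- selection_frequencies(object, level)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$label, y = .data$frequency,
                                     fill = .data$signal)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ method, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "#2c7fb8"),
                               name = "signal") +
    ggplot2::labs(x = NULL, y = "selection frequency (% of replicates)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
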
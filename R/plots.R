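#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_rect geom_hline geom_abline facet_wrap labs theme_minimal
#'   scale_colour_manual coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot the six performance scores of an evaluation
#'
#' @param object A `tricall_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot: one bar per score, faceted by prediction subset
#'   (reliable-only vs all variants).
#' @method autoplot tricall_eval
#' @export
autoplot.tricall_eval <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("ppv", "npv", "sensitivity", "specificity",
                          "accuracy", "nmcc"),
                        names_to = "score", values_to = "value")
  ggplot(long, aes(x = .data$score, y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~subset) +
    labs(x = NULL, y = "score",
         title = "Classifier performance",
         subtitle = paste0("coverage ", round(object$coverage, 3))) +
    theme_minimal()
}

#' Plot performance-cuboid face projections
#'
#' Draws the three axis-plane projections of the cuboid; the area of
#' each rectangle is one pairwise product of the normalized volume.
#'
#' @param object A `tricall_cuboid` from [cuboid_geometry()].
#' @param ... Unused.
#' @return A ggplot of the xy, xz and yz projections.
#' @method autoplot tricall_cuboid
#' @export
autoplot.tricall_cuboid <- function(object, ...) {
  f <- object$faces
  rects <- tibble(
    projection = c("PPV/NPV x Sens/Spec", "PPV/NPV x Acc/nMCC",
                   "Sens/Spec x Acc/nMCC"),
    xmin = c(-f[["npv"]], -f[["npv"]], -f[["specificity"]]),
    xmax = c(f[["ppv"]], f[["ppv"]], f[["sensitivity"]]),
    ymin = c(-f[["specificity"]], -f[["nmcc"]], -f[["nmcc"]]),
    ymax = c(f[["sensitivity"]], f[["accuracy"]], f[["accuracy"]]))
  ggplot(rects) +
    geom_rect(aes(xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
                  ymax = .data$ymax),
              fill = "steelblue", alpha = 0.4, colour = "grey20") +
    facet_wrap(~projection) +
    coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    labs(title = paste0("Performance cuboid, OPM ",
                        round(object$opm, 3)),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a forward-selection trace
#'
#' @param object A `tricall_selection` from [run_two_step_selection()].
#' @param ... Unused.
#' @return A ggplot of cross-validation accuracy against accepted
#'   forward-selection steps.
#' @method autoplot tricall_selection
#' @export
autoplot.tricall_selection <- function(object, ...) {
  tr <- object$forward_trace
  ggplot(tr, aes(x = .data$step, y = .data$accuracy)) +
    geom_line(colour = "grey40") +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$added), vjust = -0.8, size = 3) +
    labs(x = "accepted step", y = "family-aware CV accuracy",
         title = "Forward feature selection") +
    theme_minimal()
}

#' Reliability plot of tri-class predictions
#'
#' Scatter of the bootstrap spread against the mean probability, coloured
#' by the tri-class call; the unknown band is the region where the
#' Chebyshev interval straddles 0.5.
#'
#' @param predictions Tibble from [predict.tricall_ensemble()].
#' @return A ggplot.
#' @export
plot_reliability <- function(predictions) {
  k <- predictions$k[1]
  ggplot(predictions, aes(x = .data$mu, y = .data$sigma,
                          colour = .data$call)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1 / k, intercept = -0.5 / k, linetype = 2,
                colour = "grey40") +
    geom_abline(slope = -1 / k, intercept = 0.5 / k, linetype = 2,
                colour = "grey40") +
    scale_colour_manual(values = c(pathogenic = "#c0392b",
                                   neutral = "#2980b9",
                                   unknown = "grey60")) +
    labs(x = "mean bootstrap probability of pathogenicity",
         y = "bootstrap standard deviation",
         title = "Reject-option reliability gate") +
    theme_minimal()
}
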
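#' Plot the per-synapse weight trajectories of a run
#'
#' @param run A `dynsyn_run` (or its `bins` tibble).
#' @return A ggplot: weight vs bin, one line per synapse, faceted by
#'   direction.
#' @export
plot_weights <- function(run) {
  bins <- if (inherits(run, "dynsyn_run")) run$bins else run
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$weight,
                                     colour = factor(.data$synapse))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~direction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bin", y = "synaptic weight W(k)", colour = "synapse") +
    ggplot2::theme_minimal()
}

#' Plot the per-synapse coefficient of variation of a run
#'
#' @inheritParams plot_weights
#' @return A ggplot: bin CV vs bin, coloured by direction, faceted by synapse.
#' @export
plot_cv <- function(run) {
  bins <- if (inherits(run, "dynsyn_run")) run$bins else run
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$cv_B,
                                     colour = .data$direction)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~synapse, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bin", y = "bin CV", colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot the mean release probability of a run
#'
#' @inheritParams plot_weights
#' @return A ggplot: per-bin mean release probability of the presynaptic
#'   transmitters, by direction.
#' @export
plot_release <- function(run) {
  bins <- if (inherits(run, "dynsyn_run")) run$bins else run
  bins |>
    dplyr::distinct(.data$direction, .data$bin, .data$M_T_B) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin, y = .data$M_T_B,
                                 colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin", y = "mean release probability", colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot a rate sweep
#'
#' @param sweep A tibble from [rate_sweep()].
#' @return A ggplot of the average post-stabilization median weight per
#'   direction against the input rate.
#' @export
plot_sweep <- function(sweep) {
  sweep |>
    tidyr::pivot_longer(c("M_S_BA", "M_S_AB"),
                        names_to = "direction", values_to = "avg_median_weight") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lambda_hz, y = .data$avg_median_weight,
                                 colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "input rate (Hz)", y = "average of per-synapse median weights") +
    ggplot2::theme_minimal()
}

#' Autoplot a run
#'
#' @param object A `dynsyn_run`.
#' @param type One of `"weights"` (default), `"cv"`, `"release"`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot dynsyn_run
#' @export
autoplot.dynsyn_run <- function(object, type = c("weights", "cv", "release"), ...) {
  switch(match.arg(type),
         weights = plot_weights(object),
         cv = plot_cv(object),
         release = plot_release(object))
}
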
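# ggplot2 visualisations for the main result types.

#' @describeIn simulate_to_steady_state plot per-species spatial profiles
#'   (one facet per species, concentration against cell index, primordium
#'   cells shaded).
#' @param object a `spatial_profile`.
#' @param species species to show (default all seven).
#' @param ... unused.
#' @export
autoplot.spatial_profile <- function(object, species = SPECIES, ...) {
  long <- tidy(object) |> dplyr::filter(.data$species %in% !!species)
  prim <- object$cell[object$prif > 0.5]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$concentration))
  if (length(prim)) {
    p <- p + ggplot2::annotate("rect", xmin = min(prim) - 0.5, xmax = max(prim) + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$cell) +
    ggplot2::labs(x = "cell (primordium shaded)", y = "steady-state level")
}

#' @describeIn consensus plot the consensus as significance-weighted edges
#'   on a circular node layout, retained edges solid.
#' @param object a `consensus_network`.
#' @param ... unused.
#' @export
autoplot.consensus_network <- function(object, ...) {
  nodes <- attr(object, "nodes")
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[seq_along(nodes)]
  pos <- tibble(node = nodes, x = cos(theta), y = sin(theta))
  seg <- as_tibble(object) |>
    dplyr::left_join(pos, by = c(from = "node")) |>
    dplyr::left_join(pos, by = c(to = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
                   linewidth = .data$significance, linetype = !.data$retained,
                   colour = .data$sign)) +
    ggplot2::geom_label(data = pos, ggplot2::aes(x = .data$x, y = .data$y,
                                                 label = .data$node)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), limits = c(0, 1)) +
    ggplot2::scale_linetype_discrete(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @describeIn local_sensitivity tornado-style plot of the relative CUC1
#'   peak-amplitude effect of each parameter perturbation.
#' @param object a `sensitivity_report`.
#' @param top show only the `top` most influential parameters.
#' @param ... unused.
#' @export
autoplot.sensitivity_report <- function(object, top = 15L, ...) {
  keep <- object |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(effect = max(abs(.data$rel_d_peak_amplitude), na.rm = TRUE)) |>
    dplyr::slice_max(.data$effect, n = top)
  df <- dplyr::filter(object, .data$parameter %in% keep$parameter)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rel_d_peak_amplitude,
    y = stats::reorder(.data$parameter, abs(.data$rel_d_peak_amplitude)),
    fill = .data$direction)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "relative change in CUC1 peak amplitude", y = NULL,
                  fill = "perturbation")
}
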
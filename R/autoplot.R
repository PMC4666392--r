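# ggplot2 methods for step tables, pair metrics and run reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-step helical parameters
#'
#' Rise and twist against step index; the triplet pattern shows as two low
#' intra-triplet values followed by one high inter-triplet value.
#'
#' @param object A `fil_steps` tibble from [step_parameters()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fil_steps <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("axial_rise", "twist", "pp_distance"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step_index, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "step", y = NULL,
                  title = "Per-step helical parameters")
}

#' Plot base-pairing metrics
#'
#' D1 per pair, coloured by flip state.
#'
#' @param object A `fil_bp` tibble from [basepair_metrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fil_bp <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pair_index, y = .data$D1,
                               colour = .data$state)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "pair", y = "D1 (C1'-C1' distance, Å)",
                  colour = "state", title = "Base-pairing metrics")
}

#' Plot a run report
#'
#' Per-strand mean helical parameters as a faceted bar chart.
#'
#' @param object A `fil_run_report` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fil_run_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object$strands),
                              c("mean_rise", "mean_twist", "mean_radius",
                                "extension"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strand, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-strand means (site-II region)")
}

#' Plot a structure projection
#'
#' Orthographic projection of the atoms, coloured by chain. `plane = "xz"`
#' (default) shows the helix side view, `"xy"` the view down the axis.
#'
#' @param structure A [fil_structure()].
#' @param plane `"xz"`, `"yz"` or `"xy"`.
#' @param atoms Atom names to draw (default: phosphates only).
#' @return A ggplot.
#' @export
plot_structure <- function(structure, plane = c("xz", "yz", "xy"),
                           atoms = "P") {
  plane <- match.arg(plane)
  s <- as_tibble(as_fil_structure(structure))
  s <- s[s$atom %in% atoms, ]
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                  colour = .data$chain)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Structure projection",
                  x = paste0(ax[1], " (Å)"), y = paste0(ax[2], " (Å)"))
}
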
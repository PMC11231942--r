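# ggplot2 renderings of phase diagrams, difference maps, trajectories and
# lattice snapshots. All functions return ggplot objects; save with ggsave().

#' Heatmap of a phase diagram
#'
#' Renders a lattice or mean-field phase diagram as an `alpha1` x `alpha2`
#' tile map. The fill scale is fixed to \[0, 1\] so diagrams are comparable.
#' For mean-field diagrams, `overlay_boundaries` adds the two closed-form
#' regime-boundary curves (the cheater-invasion bound and the emission
#' viability threshold).
#'
#' @param diagram A tibble from [phase_diagram_lattice()] or
#'   [phase_diagram_meanfield()].
#' @param value Column to map to fill (default `mean_frequency` if present,
#'   else `stable_density`).
#' @param overlay_boundaries `NULL`, or a [bvoc_params()] supplying
#'   `p`, `c`, `n` for the analytic boundary curves.
#' @return A ggplot object.
#' @examples
#' pd <- phase_diagram_meanfield(seq(0.1, 0.9, 0.1), seq(0.1, 0.9, 0.1))
#' plot_phase_diagram(pd, overlay_boundaries = bvoc_params())
#' @export
plot_phase_diagram <- function(diagram, value = NULL,
                               overlay_boundaries = NULL) {
  value <- value %||%
    if ("mean_frequency" %in% names(diagram)) "mean_frequency" else "stable_density"
  if (!all(c("alpha1", "alpha2", value) %in% names(diagram)))
    abort(sprintf("`diagram` must have columns alpha1, alpha2 and `%s`.", value))
  p <- ggplot2::ggplot(diagram, ggplot2::aes(x = .data$alpha1, y = .data$alpha2,
                                             fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "emitter\nfrequency") +
    ggplot2::labs(x = expression(alpha[1] ~ "(intra-communication)"),
                  y = expression(alpha[2] ~ "(inter-communication)")) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(overlay_boundaries)) {
    pb <- overlay_boundaries
    a2 <- seq(min(diagram$alpha2), max(diagram$alpha2), length.out = 200)
    lower <- (a2^pb$n * pb$p - pb$c) / (a2^pb$n * pb$p * (1 - pb$c))
    curves <- dplyr::bind_rows(
      tibble(alpha1 = lower, alpha2 = a2, curve = "cheater invasion bound"),
      tibble(alpha1 = emission_viability_threshold(pb$p, pb$c),
             alpha2 = a2, curve = "viability threshold")
    ) |> dplyr::filter(.data$alpha1 > 0, .data$alpha1 < 1)
    p <- p + ggplot2::geom_path(
      data = curves,
      ggplot2::aes(x = .data$alpha1, y = .data$alpha2, linetype = .data$curve),
      inherit.aes = FALSE, color = "white"
    )
  }
  p
}

#' Difference map between two signaling ranges
#'
#' Diverging-color tile map of the cellwise difference in mean emitter
#' frequency from [range_comparison()]; red cells mean the short signaling
#' range favors emitters.
#'
#' @param comparison Output of [range_comparison()].
#' @return A ggplot object.
#' @export
plot_range_difference <- function(comparison) {
  if (!all(c("alpha1", "alpha2", "difference") %in% names(comparison)))
    abort("`comparison` must have columns alpha1, alpha2, difference.")
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$alpha1, y = .data$alpha2,
                                           fill = .data$difference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "grey40", mid = "white", high = "firebrick",
                                  limits = c(-1, 1), name = "frequency\ndifference") +
    ggplot2::labs(x = expression(alpha[1]), y = expression(alpha[2])) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Lattice snapshot
#'
#' One tile per site: emitters dark blue, non-emitters white, vacant sites
#' grey (transient snapshots may contain them).
#'
#' @param state Lattice state matrix.
#' @return A ggplot object.
#' @examples
#' set.seed(1)
#' plot_lattice(init_lattice(20, 0.3, 0.3))
#' @export
plot_lattice <- function(state) {
  ggplot2::ggplot(lattice_tbl(state),
                  ggplot2::aes(x = .data$j, y = .data$i, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(emitter = "navy", nonemitter = "white", vacant = "grey80"),
      drop = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' Population trajectory of a simulation
#'
#' Per-step counts of emitters, non-emitters and vacant sites.
#'
#' @param sim A `bvoc_sim` object from [run_simulation()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(sim) {
  stopifnot(inherits(sim, "bvoc_sim"))
  long <- tidyr::pivot_longer(sim$counts, -"step",
                              names_to = "type", values_to = "count") |>
    dplyr::mutate(type = sub("^n_", "", .data$type))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$count,
                                     color = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(emitter = "navy", nonemitter = "goldenrod", vacant = "grey60")
    ) +
    ggplot2::labs(x = "step", y = "sites") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bvoc_sim <- function(object, ...) plot_trajectory(object)

#' Bar chart of the four range combinations
#'
#' Mean final emitter frequency with standard-deviation error bars, one bar
#' per `(r_bvoc, r_d)` combination, from [dispersal_comparison()].
#'
#' @param comparison Output of [dispersal_comparison()].
#' @return A ggplot object.
#' @export
plot_dispersal_comparison <- function(comparison) {
  if (!all(c("r_bvoc", "r_d", "mean_frequency", "sd_frequency") %in%
           names(comparison)))
    abort("`comparison` must come from dispersal_comparison().")
  df <- dplyr::mutate(comparison,
                      combo = sprintf("r[BVOC]==%d~r[D]==%d", .data$r_bvoc, .data$r_d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combo, y = .data$mean_frequency,
                                   fill = factor(.data$r_d))) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_frequency - .data$sd_frequency),
                   ymax = pmin(1, .data$mean_frequency + .data$sd_frequency)),
      width = 0.2
    ) +
    ggplot2::scale_x_discrete(labels = function(l) parse(text = l)) +
    ggplot2::scale_fill_manual(values = c(`1` = "goldenrod", `2` = "darkorange"),
                               name = expression(r[D])) +
    ggplot2::labs(x = NULL, y = "mean emitter frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
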
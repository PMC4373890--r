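# ggplot2 helpers for the three result types.

#' Plot a population time series
#'
#' Total population and per-lineage counts against simulated time.
#'
#' @param series population series tibble (from [run_scenario()] or
#'   [run_steps()]).
#' @param lineages include per-lineage curves.
#' @return a ggplot object.
#' @export
plot_population <- function(series, lineages = TRUE) {
  stopifnot(is.data.frame(series))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$sim_hours)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_total), linewidth = 0.7) +
    ggplot2::labs(x = "simulated time (h)", y = "cells",
                  title = "Epithelial population") +
    ggplot2::theme_minimal()
  if (lineages) {
    long <- rbind(
      data.frame(sim_hours = series$sim_hours, n = series$n_stem,
                 lineage = "stem"),
      data.frame(sim_hours = series$sim_hours, n = series$n_progenitor,
                 lineage = "progenitor"),
      data.frame(sim_hours = series$sim_hours, n = series$n_enterocyte,
                 lineage = "enterocyte"),
      data.frame(sim_hours = series$sim_hours, n = series$n_metaplastic,
                 lineage = "metaplastic"))
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$n, colour = .data$lineage), linewidth = 0.4)
  }
  p
}

#' Plot morphogen gradient profiles
#'
#' Mean concentration against the crypt-base -> villus-tip axis row, one
#' line per mediator.
#'
#' @param profiles named list of tibbles from [gradient_profile()] (names
#'   are mediator ids).
#' @return a ggplot object.
#' @export
plot_gradient <- function(profiles) {
  long <- do.call(rbind, lapply(names(profiles), function(m)
    data.frame(axis_row = profiles[[m]]$axis_row,
               mean_concentration = profiles[[m]]$mean_concentration,
               mediator = m)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$axis_row,
                                     y = .data$mean_concentration,
                                     colour = .data$mediator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axis row (0 = crypt base)",
                  y = "mean relative concentration",
                  title = "Crypt-villus morphogen gradients") +
    ggplot2::theme_minimal()
}

#' Plot the axial metaplasia gradient
#'
#' Final mean villus height and metaplastic unit fraction against axial
#' position (proximal -> terminal).
#'
#' @param report output of [pouchitis_gradient_report()].
#' @return a ggplot object.
#' @export
plot_axial_gradient <- function(report) {
  tb <- report$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$axial_mm_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_villus_height)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_villus_height)) +
    ggplot2::labs(x = "axial position (mm, terminal at right)",
                  y = "mean villus height (rows)",
                  title = sprintf(
                    "Axial villus-height gradient (Spearman rho = %.2f)",
                    report$spearman_rho)) +
    ggplot2::theme_minimal()
}
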
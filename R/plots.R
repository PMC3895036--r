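#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   facet_wrap labs theme_minimal
#' @importFrom rlang .data
NULL

#' Plot a simulation trajectory
#'
#' One panel per trajectory variable against simulation year.
#'
#' @param object A [simulate_landscape()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"year",
                              names_to = "variable", values_to = "value")
  ggplot(long, aes(x = .data$year, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "Simulation year", y = NULL,
         title = "Landscape dynamics under the management regime") +
    theme_minimal()
}

#' Plot the hypervolume convergence of an optimization run
#'
#' @param object An [nsga2()] / [optimize_regimes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_nsga2 <- function(object, ...) {
  if (is.null(object$hypervolume)) abort("Run was built without hypervolume tracking.")
  ggplot(object$hypervolume, aes(x = .data$generation, y = .data$hypervolume)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "Generation", y = "Dominated hypervolume (archive)",
         title = "Convergence of the optimization") +
    theme_minimal()
}

#' Level diagrams of a frontier
#'
#' One panel per objective: raw objective value on the x axis, weighted
#' distance to the ideal point on the y axis (shared across panels).
#'
#' @param frontier Tibble with the six objective columns; extra columns such
#'   as `k` are used for colour when present.
#' @param weights Passed to [level_scores()].
#' @return A ggplot object.
#' @export
plot_level_diagram <- function(frontier, weights = c(cost = 6, fire = 2, biodiversity = 3)) {
  long <- level_diagram_data(frontier, weights)
  if ("k" %in% names(frontier)) {
    frontier$solution <- seq_len(nrow(frontier))
    long <- dplyr::left_join(long, frontier[, c("solution", "k")], by = "solution")
    p <- ggplot(long, aes(x = .data$raw, y = .data$distance_to_ideal,
                          colour = factor(.data$k)))
  } else {
    p <- ggplot(long, aes(x = .data$raw, y = .data$distance_to_ideal))
  }
  p + geom_point(alpha = 0.7) +
    facet_wrap(~objective, scales = "free_x") +
    labs(x = "Objective value", y = "Distance to ideal point",
         colour = "Groups") +
    theme_minimal()
}

#' Pairwise objective scatterplot
#'
#' @param frontier Tibble with the six objective columns.
#' @param x,y Objective names (strings).
#' @return A ggplot object.
#' @export
plot_objective_scatter <- function(frontier, x = "cost", y = "fuel_load") {
  stopifnot(x %in% obj_names(), y %in% obj_names())
  aes_args <- if ("k" %in% names(frontier)) {
    aes(x = .data[[x]], y = .data[[y]], colour = factor(.data$k))
  } else {
    aes(x = .data[[x]], y = .data[[y]])
  }
  ggplot(frontier, aes_args) + geom_point(alpha = 0.7) +
    labs(colour = "Groups") + theme_minimal()
}

#' Plot a regime's management-interval density
#'
#' @param object A [solution_density()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_density <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$density)) +
    geom_line() +
    labs(x = "Management interval (years)", y = "Density",
         title = sprintf("Regime density (bandwidth %g y)", attr(object, "bandwidth"))) +
    theme_minimal()
}

#' Plot a principal-coordinate embedding
#'
#' @param object A [pcoa()] result.
#' @param labels Optional point labels/groups for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_pcoa <- function(object, labels = NULL, ...) {
  d <- object$coordinates
  if (!is.null(labels)) d$label <- labels
  ve <- 100 * object$variance_explained
  p <- if (!is.null(labels)) {
    ggplot(d, aes(x = .data$axis_1, y = .data$axis_2, colour = .data$label))
  } else {
    ggplot(d, aes(x = .data$axis_1, y = .data$axis_2))
  }
  p + geom_point() +
    labs(x = sprintf("PCo 1 (%.1f%%)", ve[1]),
         y = sprintf("PCo 2 (%.1f%%)", ve[2]), colour = NULL) +
    theme_minimal()
}

#' Plot re-simulated regime dynamics with uncertainty bands
#'
#' Mean plus/minus one standard deviation per year, one panel per variable.
#'
#' @param rescan A [compromise_rescan()] result.
#' @param variables Variables to show (default: the age-class areas).
#' @return A ggplot object.
#' @export
plot_rescan <- function(rescan, variables = c("pct_young", "pct_mid", "pct_late")) {
  d <- rescan[rescan$variable %in% variables, ]
  ggplot(d, aes(x = .data$year, y = .data$mean,
                colour = .data$variable, fill = .data$variable)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                alpha = 0.2, colour = NA) +
    geom_line() +
    facet_wrap(~factor(.data$regime_id), labeller = "label_both") +
    labs(x = "Simulation year", y = "% of landscape area",
         colour = "Age class", fill = "Age class") +
    theme_minimal()
}
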
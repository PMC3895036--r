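#' Level-diagram scores: weighted distance to the ideal point
#'
#' Each frontier solution is scored with its Euclidean distance to the
#' theoretical ideal point where every objective attains its best value over
#' the frontier. Objectives are first range-standardized to \[0, 1\] (best = 0,
#' worst = 1) and then weighted by objective group - 6 for the single cost
#' objective, 2 for each of the three fire-risk objectives, 3 for each of the
#' two biodiversity objectives - so the three groups carry equal summed weight.
#' The distance is `sqrt(sum((w_i * z_i)^2))`; a solution worst in everything
#' scores `sqrt(6^2 + 3*2^2 + 2*3^2) = sqrt(66)`.
#'
#' @param frontier Tibble with the six display-form objective columns (e.g.
#'   `$frontier` of [optimize_regimes()] or [combine_frontiers()]).
#' @param weights Named per-group weights (default `c(cost = 6, fire = 2,
#'   biodiversity = 3)`).
#' @return The input tibble with added columns `z_<objective>` (standardized
#'   values) and `distance_to_ideal`.
#' @export
level_scores <- function(frontier, weights = c(cost = 6, fire = 2, biodiversity = 3)) {
  info <- objective_info()
  if (!all(info$objective %in% names(frontier))) {
    abort("`frontier` must contain all six objective columns.")
  }
  w <- unname(weights[info$group])
  z <- matrix(0, nrow(frontier), nrow(info),
              dimnames = list(NULL, paste0("z_", info$objective)))
  for (i in seq_len(nrow(info))) {
    x <- frontier[[info$objective[i]]]
    r <- range(x)
    if (diff(r) > 0) {
      z[, i] <- if (info$direction[i] == "min") (x - r[1]) / diff(r)
                else (r[2] - x) / diff(r)
    }
  }
  out <- dplyr::bind_cols(frontier, as_tibble(z))
  out$distance_to_ideal <- sqrt(as.vector((z^2) %*% w^2))
  out
}

#' Long-form level-diagram data
#'
#' Tidy export for level-diagram plotting: one row per (solution, objective)
#' with the raw value, the standardized value and the solution's overall
#' distance to the ideal point (constant across objectives).
#'
#' @inheritParams level_scores
#' @return Tibble with columns `solution`, `objective`, `raw`, `standardized`,
#'   `distance_to_ideal`.
#' @export
level_diagram_data <- function(frontier, weights = c(cost = 6, fire = 2, biodiversity = 3)) {
  scored <- level_scores(frontier, weights)
  if (!"solution" %in% names(scored)) scored$solution <- seq_len(nrow(scored))
  raw <- tidyr::pivot_longer(scored[, c("solution", obj_names())],
                             -"solution", names_to = "objective", values_to = "raw")
  zs <- scored[, paste0("z_", obj_names())]
  names(zs) <- obj_names()
  zs$solution <- scored$solution
  std <- tidyr::pivot_longer(zs, -"solution", names_to = "objective",
                             values_to = "standardized")
  out <- dplyr::left_join(raw, std, by = c("solution", "objective"))
  dplyr::left_join(out, scored[, c("solution", "distance_to_ideal")], by = "solution")
}

#' Restriction scenarios on the Pareto frontier
#'
#' A scenario is a set of objective constraints expressing decision-maker
#' preferences; [apply_scenario()] keeps the frontier solutions satisfying all
#' of them. Built-in scenarios:
#' * `"cost5"` / `"cost10"`: funding agency - annual managed area within 5% (or
#'   10%) plus or minus 0.375 percentage points.
#' * `"fire"`: forest management agency - each fire-risk objective within the
#'   25% best frontier results.
#' * `"biodiversity"`: conservation agency - at least 9.9% of the landscape
#'   maintained in each of the mid- and late-successional classes.
#' * `"compromise"`: all preferences relaxed - cost at most 20%, fire-risk
#'   objectives within the best 60%, and at least 9% in each age class.
#' * `"none"`: no constraints.
#'
#' Constraint types: `band` (value within `center` plus or minus `halfwidth`),
#' `percentile` (within the best fraction `q` of the input frontier, in the
#' objective's display direction; thresholds use linear-interpolation
#' quantiles), `threshold` (`>=` or `<=` a fixed value).
#'
#' @param name Built-in scenario name.
#' @param constraints For `new_scenario()`: list of constraints built with
#'   [scenario_constraint()].
#' @return A `fs_scenario` object.
#' @export
#' @examples
#' scenario("compromise")
scenario <- function(name = c("none", "cost5", "cost10", "fire",
                              "biodiversity", "compromise")) {
  name <- match.arg(name)
  cons <- switch(
    name,
    none = list(),
    cost5 = list(scenario_constraint("cost", "band", center = 5, halfwidth = 0.375)),
    cost10 = list(scenario_constraint("cost", "band", center = 10, halfwidth = 0.375)),
    fire = list(
      scenario_constraint("fuel_load", "percentile", q = 0.25),
      scenario_constraint("edge_contrast", "percentile", q = 0.25),
      scenario_constraint("skewness", "percentile", q = 0.25)
    ),
    biodiversity = list(
      scenario_constraint("mid_area", "threshold", op = ">=", value = 9.9),
      scenario_constraint("late_area", "threshold", op = ">=", value = 9.9)
    ),
    compromise = list(
      scenario_constraint("cost", "threshold", op = "<=", value = 20),
      scenario_constraint("fuel_load", "percentile", q = 0.6),
      scenario_constraint("edge_contrast", "percentile", q = 0.6),
      scenario_constraint("skewness", "percentile", q = 0.6),
      scenario_constraint("mid_area", "threshold", op = ">=", value = 9),
      scenario_constraint("late_area", "threshold", op = ">=", value = 9)
    )
  )
  new_scenario(name, cons)
}

#' @rdname scenario
#' @export
new_scenario <- function(name, constraints) {
  ok <- vapply(constraints, function(cn) cn$objective %in% obj_names(), TRUE)
  if (!all(ok)) abort("Every constraint must reference one of the six objectives.")
  structure(list(name = name, constraints = constraints), class = "fs_scenario")
}

#' @rdname scenario
#' @param objective One of the six objective names.
#' @param type `"band"`, `"percentile"` or `"threshold"`.
#' @param ... Parameters: `center`/`halfwidth` (band), `q` (percentile, the
#'   best fraction kept), `op`/`value` (threshold).
#' @export
scenario_constraint <- function(objective, type = c("band", "percentile", "threshold"), ...) {
  type <- match.arg(type)
  structure(list(objective = objective, type = type, params = list(...)),
            class = "fs_constraint")
}

#' @export
print.fs_scenario <- function(x, ...) {
  cat(sprintf("<fs_scenario> '%s' (%d constraints)\n", x$name, length(x$constraints)))
  for (cn in x$constraints) {
    p <- cn$params
    desc <- switch(cn$type,
      band = sprintf("within %g +/- %g", p$center, p$halfwidth),
      percentile = sprintf("within the best %g%%", 100 * p$q),
      threshold = sprintf("%s %g", p$op, p$value))
    cat(sprintf("  %s: %s\n", cn$objective, desc))
  }
  invisible(x)
}

#' Filter a frontier by a restriction scenario
#'
#' Percentile thresholds are computed over the *input* frontier (linear
#' interpolation quantiles), then each solution is kept only if it satisfies
#' every constraint. The result may be empty; adding constraints never enlarges
#' it.
#'
#' @param frontier Tibble with the six objective columns (display form).
#' @param scen A [scenario()] object.
#' @return The filtered tibble, with a `scenario` column recording the name.
#' @export
apply_scenario <- function(frontier, scen) {
  stopifnot(inherits(scen, "fs_scenario"))
  keep <- rep(TRUE, nrow(frontier))
  info <- objective_info()
  for (cn in scen$constraints) {
    x <- frontier[[cn$objective]]
    dir <- info$direction[info$objective == cn$objective]
    p <- cn$params
    keep <- keep & switch(
      cn$type,
      band = abs(x - p$center) <= p$halfwidth,
      percentile = if (dir == "min") {
        x <= stats::quantile(x, p$q, names = FALSE)
      } else {
        x >= stats::quantile(x, 1 - p$q, names = FALSE)
      },
      threshold = if (p$op == ">=") x >= p$value else x <= p$value
    )
  }
  out <- frontier[keep, , drop = FALSE]
  out$scenario <- scen$name
  out
}

#' Re-simulate regimes and summarize per-year dynamics
#'
#' Implements each regime in `n_sims` independent random landscapes (a fresh
#' landscape, owner allocation and uncertainty draws per simulation) and
#' returns per-year means and standard deviations of every trajectory variable
#' (objective variables plus the young/mid/late age-class areas). This is the
#' decision-support step used to examine the temporal dynamics produced by
#' compromise solutions.
#'
#' @param regimes A [management_regime()] or list of them.
#' @param n_sims Simulations per regime (default 100).
#' @param n_rows,n_cols Landscape dimensions for the fresh random landscapes.
#' @param dist An [area_distribution()].
#' @param model An [uncertainty_model()].
#' @param horizon Simulation years (default 100).
#' @param curve A [biomass_curve()].
#' @param seed Integer seed.
#' @return A tibble with columns `regime_id`, `year`, `variable`, `mean`, `sd`.
#' @export
compromise_rescan <- function(regimes, n_sims = 100, n_rows = 50, n_cols = 50,
                              dist = area_distribution(),
                              model = uncertainty_model(), horizon = 100,
                              curve = biomass_curve(), seed = 1) {
  if (inherits(regimes, "management_regime")) regimes <- list(regimes)
  purrr::map_dfr(seq_along(regimes), function(ri) {
    sims <- purrr::map_dfr(seq_len(n_sims), function(s) {
      sim_seed <- derive_seed(seed, ri * 10000 + s)
      l <- hex_landscape(n_rows, n_cols, dist, seed = sim_seed)
      tr <- simulate_landscape(l, regimes[[ri]], model = model,
                               horizon = horizon, curve = curve,
                               seed = derive_seed(sim_seed, 1))
      tr$sim <- s
      tr
    })
    long <- tidyr::pivot_longer(sims, -c("year", "sim"),
                                names_to = "variable", values_to = "value")
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$year, .data$variable),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop")
    out$regime_id <- ri
    out[, c("regime_id", "year", "variable", "mean", "sd")]
  })
}

#' Kernel density of a regime over the management-interval axis
#'
#' A regime is summarized as a probability density over management intervals:
#' a mixture of Gaussian kernels centred at the group intervals (bandwidth 5
#' years by default), with mixture weights equal to the proportions of
#' landowners. No-management groups enter at interval 100. Densities are
#' evaluated on a fixed grid spanning \[3, 100\] extended by four bandwidths
#' (step 0.1), without truncation or renormalization, so the trapezoid
#' integral is 1 up to a negligible tail.
#'
#' @param regime A [management_regime()].
#' @param bandwidth Kernel standard deviation in years (default 5).
#' @param grid Evaluation grid (default `seq(-17, 120, by = 0.1)`).
#' @return A `fs_density` tibble with columns `x` (interval, years) and
#'   `density`, carrying `bandwidth` and the regime as attributes.
#' @export
solution_density <- function(regime, bandwidth = 5,
                             grid = seq(-17, 120, by = 0.1)) {
  stopifnot(inherits(regime, "management_regime"))
  dens <- rep(0, length(grid))
  for (g in seq_len(regime$n_groups)) {
    dens <- dens + regime$proportions[g] *
      stats::dnorm(grid, mean = regime$intervals[g], sd = bandwidth)
  }
  structure(tibble(x = grid, density = dens),
            class = c("fs_density", class(tibble())),
            bandwidth = bandwidth, regime = regime)
}

#' Density-intersection distance between two regimes
#'
#' One minus the intersection of the two density functions (the trapezoid
#' integral of their pointwise minimum), a distance in \[0, 1\]: 0 for
#' identical regimes, approaching 1 for regimes with non-overlapping interval
#' profiles.
#'
#' @param d1,d2 [solution_density()] results on the same grid.
#' @return Distance in \[0, 1\].
#' @export
density_distance <- function(d1, d2) {
  if (!isTRUE(all.equal(d1$x, d2$x))) {
    abort("Densities must be evaluated on the same grid.")
  }
  m <- pmin(d1$density, d2$density)
  dx <- diff(d1$x)
  overlap <- sum((m[-1] + m[-length(m)]) / 2 * dx)
  min(max(1 - overlap, 0), 1)
}

#' Pairwise density-distance matrix for a set of regimes
#'
#' @param regimes List of [management_regime()] objects.
#' @param bandwidth,grid Passed to [solution_density()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
density_distance_matrix <- function(regimes, bandwidth = 5,
                                    grid = seq(-17, 120, by = 0.1)) {
  dens <- lapply(regimes, solution_density, bandwidth = bandwidth, grid = grid)
  n <- length(dens)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- density_distance(dens[[i]], dens[[j]])
    }
  }
  D
}

#' Principal Coordinate Analysis (classical multidimensional scaling)
#'
#' Embeds a distance matrix in a low-dimensional Euclidean space: the squared
#' distances are double-centred, eigendecomposed, and coordinates scaled by the
#' square roots of the positive eigenvalues. For a Euclidean-embeddable matrix
#' the full coordinate space reproduces the input distances exactly; negative
#' eigenvalues (non-Euclidean input) are dropped from both the coordinates and
#' the variance-explained denominator.
#'
#' @param D Square, symmetric, zero-diagonal distance matrix.
#' @param k Number of coordinates to report (default 2).
#' @return A `fs_pcoa` list: `coordinates` (tibble with `axis_1`, `axis_2`,
#'   ...), `all_coordinates` (matrix over all positive eigenvalues),
#'   `eigenvalues`, `variance_explained` (fractions of the positive-eigenvalue
#'   total for the reported axes).
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(abs(diag(D)) > 1e-12)) {
    abort("`D` must be square, symmetric with zero diagonal.")
  }
  n <- nrow(D)
  if (n < 2) abort("`D` must have at least two rows.")
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(max(eig), 0) * 1e-12 & eig > 0)
  pts <- fit$points
  all_coords <- pts[, seq_len(min(length(pos), ncol(pts))), drop = FALSE]
  k_eff <- min(k, ncol(all_coords))
  coords <- matrix(0, n, k)
  if (k_eff > 0) coords[, seq_len(k_eff)] <- all_coords[, seq_len(k_eff)]
  colnames(coords) <- paste0("axis_", seq_len(k))
  ve <- rep(NA_real_, k)
  if (k_eff > 0) ve[seq_len(k_eff)] <- eig[seq_len(k_eff)] / sum(eig[pos])
  structure(list(coordinates = as_tibble(coords),
                 all_coordinates = all_coords,
                 eigenvalues = eig,
                 variance_explained = ve,
                 degenerate = length(pos) == 0),
            class = "fs_pcoa")
}

#' @export
print.fs_pcoa <- function(x, ...) {
  cat(sprintf("<fs_pcoa> %d points; axis variance explained: %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}
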
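#' The six landscape-level objectives
#'
#' Metadata for the objective set: management cost (% of landscape cleared per
#' year, averaged over all years, minimized), maximum annual fuel load (kg/ha,
#' minimized), minimum annual edge contrast ((kg/ha)^2, maximized), minimum
#' annual fuel concentration (biomass skewness, maximized), and minimum annual
#' area of mid- (30-60 y) and late-successional (>60 y) understories (% of
#' landscape, maximized). Annual extremes (not means) are used so that single
#' years of extreme fire risk are not averaged away.
#'
#' @return A tibble with columns `objective`, `direction` (`min`/`max` in
#'   display form), `group` (`cost`, `fire`, `biodiversity`) and `weight` (the
#'   level-diagram weight: 6 for cost, 2 per fire objective, 3 per biodiversity
#'   objective).
#' @export
objective_info <- function() {
  tibble(
    objective = c("cost", "fuel_load", "edge_contrast", "skewness",
                  "mid_area", "late_area"),
    direction = c("min", "min", "max", "max", "max", "max"),
    group = c("cost", "fire", "fire", "fire", "biodiversity", "biodiversity"),
    weight = c(6, 2, 2, 2, 3, 3)
  )
}

obj_names <- function() objective_info()$objective

# +1 for minimized, -1 for maximized objectives (display -> canonical sign).
obj_signs <- function() ifelse(objective_info()$direction == "min", 1, -1)

#' Convert objectives between display and canonical minimization form
#'
#' Internally all six objectives are handled as minimization values: the four
#' maximization objectives are negated. `objectives_canonical()` maps a display
#' tibble to a numeric matrix in canonical form; `objectives_display()` is the
#' inverse bijection.
#'
#' @param objectives A tibble with the six objective columns (display form).
#' @return `objectives_canonical()`: numeric matrix (rows = solutions, columns
#'   = objectives); `objectives_display()`: tibble in display form.
#' @export
objectives_canonical <- function(objectives) {
  m <- as.matrix(objectives[, obj_names(), drop = FALSE])
  sweep(m, 2, obj_signs(), `*`)
}

#' @rdname objectives_canonical
#' @param canonical Numeric matrix in canonical minimization form.
#' @export
objectives_display <- function(canonical) {
  canonical <- rbind(canonical)
  m <- sweep(canonical, 2, obj_signs(), `*`)
  colnames(m) <- obj_names()
  as_tibble(m)
}

#' Mean fuel load across the landscape
#'
#' Arithmetic mean of per-cell understory biomass; since cells are 1 ha this is
#' the landscape biomass per hectare (kg/ha).
#'
#' @param b Numeric vector of per-cell biomass values (kg/ha); non-empty.
#' @return Mean biomass (kg/ha).
#' @export
mean_fuel_load <- function(b) {
  if (length(b) == 0) abort("`b` must be non-empty.")
  mean(b)
}

#' Edge contrast of fuel loads ("root mean square slope")
#'
#' Population variance of the absolute differences in biomass between all
#' unordered pairs of adjacent cells, each pair counted once. High values
#' indicate strong spatial discontinuity of fuels (compartmentation); a
#' uniform landscape scores 0.
#'
#' @param b Numeric vector of per-cell biomass values.
#' @param pairs Two-column integer matrix of adjacent cell pairs (as in
#'   `hex_grid()$pairs`); at least one pair.
#' @return Variance of absolute adjacent differences ((kg/ha)^2).
#' @export
#' @examples
#' edge_contrast(c(0, 1, 4), cbind(c(1, 2), c(2, 3))) # |d| = {1, 3} -> var 1
edge_contrast <- function(b, pairs) {
  pairs <- rbind(pairs)
  if (nrow(pairs) == 0) abort("`pairs` must contain at least one adjacent pair.")
  d <- abs(b[pairs[, 1]] - b[pairs[, 2]])
  mean(d^2) - mean(d)^2
}

#' Fuel concentration (surface skewness)
#'
#' Moment coefficient of skewness g1 = m3 / m2^(3/2) of per-cell biomass,
#' using population (biased) moments. Largest when most cells carry little
#' fuel and a few carry much. Returns 0 for zero-variance input.
#'
#' @param b Numeric vector of per-cell biomass values; at least 3 values.
#' @return Dimensionless skewness coefficient.
#' @export
#' @examples
#' fuel_skewness(c(0, 0, 0, 1)) # ~1.1547
fuel_skewness <- function(b) {
  if (length(b) < 3) abort("`b` must contain at least 3 values.")
  mu <- mean(b)
  m2 <- mean((b - mu)^2)
  if (m2 == 0) return(0)
  mean((b - mu)^3) / m2^1.5
}

#' Area fraction in an understory age class
#'
#' @param age Integer vector of per-cell understory ages (years).
#' @param lo,hi Inclusive class bounds in years (`hi = Inf` for open classes;
#'   the late-successional class ">60 years" is `lo = 61, hi = Inf` on integer
#'   ages).
#' @return Percentage of cells with `lo <= age <= hi`.
#' @export
age_class_fraction <- function(age, lo, hi = Inf) {
  if (lo >= hi && !(lo == hi)) abort("`lo` must not exceed `hi`.")
  if (length(age) == 0) return(0)
  100 * mean(age >= lo & age <= hi)
}

#' Summarize a simulation trajectory into the six objectives
#'
#' Cost is the mean managed fraction over *all* simulated years; all other
#' objectives discard the first `burn_in` years (landscape "adaptation" to the
#' new regime) and take the worst-case annual value in display form: the
#' maximum for fuel load and the minimum for edge contrast, skewness and the
#' two age-class areas.
#'
#' @param trajectory A [simulate_landscape()] result.
#' @param burn_in Years discarded at the start for all objectives except cost
#'   (default 20); must be smaller than the horizon.
#' @return A one-row tibble with columns `cost`, `fuel_load`, `edge_contrast`,
#'   `skewness`, `mid_area`, `late_area` (display form).
#' @export
objectives_from_trajectory <- function(trajectory, burn_in = 20) {
  stopifnot(inherits(trajectory, "fs_trajectory"))
  horizon <- attr(trajectory, "horizon")
  if (burn_in < 0 || horizon <= burn_in) {
    abort("`burn_in` must be non-negative and smaller than the horizon.")
  }
  post <- trajectory$year >= burn_in
  tibble(
    cost = mean(trajectory$pct_managed),
    fuel_load = max(trajectory$mean_biomass[post]),
    edge_contrast = min(trajectory$edge_contrast[post]),
    skewness = min(trajectory$skewness[post]),
    mid_area = min(trajectory$pct_mid[post]),
    late_area = min(trajectory$pct_late[post])
  )
}

#' Worst-case aggregation over replicate evaluations
#'
#' A candidate regime is evaluated on several replicate random landscapes; its
#' objective vector is the componentwise *worst* result (the maximum in
#' canonical minimization form), so that solutions are judged by their worst
#' replicate, not their average.
#'
#' @param objectives Tibble of display-form objective rows (one per replicate);
#'   at least one row.
#' @return One-row display-form tibble.
#' @export
#' @examples
#' reps <- tibble::tibble(cost = c(1, 2), fuel_load = c(5, 4),
#'   edge_contrast = c(3, 1), skewness = c(0.2, 0.5),
#'   mid_area = c(10, 12), late_area = c(9, 7))
#' aggregate_replicates(reps) # cost 2, fuel 5, edge 1, skew 0.2, mid 10, late 7
aggregate_replicates <- function(objectives) {
  if (nrow(objectives) == 0) abort("`objectives` must contain at least one row.")
  can <- objectives_canonical(objectives)
  worst <- apply(can, 2, max)
  objectives_display(matrix(worst, nrow = 1))
}

#' Write objective vectors to CSV or JSON
#'
#' Values are written in display form; a `canonical` flag records the
#' convention so readers can reconstruct the minimization form.
#'
#' @param objectives Display-form objective tibble.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_objectives <- function(objectives, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(canonical = FALSE, objectives = objectives),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- objectives
    out$canonical <- FALSE
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
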
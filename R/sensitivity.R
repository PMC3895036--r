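#' Default sweep levels for the a-priori-assumption analyses
#'
#' The two axes along which the study's prior assumptions are varied:
#' landholding-area Gamma (mean, variance) pairs 20/100, 60/900, 100/2500,
#' 140/4900, 200/10000, and implementation-uncertainty maximum variances (the
#' variance at the 100-year interval) 1, 5, 10, 50, 100, 500 and 1000.
#'
#' @param axis `"landholding_area"` or `"uncertainty"`.
#' @return For the area axis, a list of `c(mean, variance)` pairs; for the
#'   uncertainty axis, a numeric vector of maximum variances.
#' @export
sweep_levels <- function(axis = c("landholding_area", "uncertainty")) {
  axis <- match.arg(axis)
  if (axis == "landholding_area") {
    list(c(20, 100), c(60, 900), c(100, 2500), c(140, 4900), c(200, 10000))
  } else {
    c(1, 5, 10, 50, 100, 500, 1000)
  }
}

#' Run a sensitivity sweep of simulation-optimizations
#'
#' Repeats the full simulation-optimization once per level of a swept
#' parameter, with everything else held fixed: either the landholding-area
#' distribution used to generate the landscape pool, or the implementation-
#' uncertainty model. Each level regenerates its own pool (the area axis
#' requires it) and derives its seeds from the base seed, so levels are
#' independent but jointly reproducible. The full-scale design uses 400
#' generations and 12 replicate landscapes per evaluation; the scaled-down
#' defaults here follow the desk preset.
#'
#' @param axis `"landholding_area"` or `"uncertainty"`.
#' @param levels Sweep levels (see [sweep_levels()]); defaults to the study's
#'   printed levels.
#' @param n_rows,n_cols,pool_size Landscape-pool specification per level.
#' @param k Strategy (number of landowner groups).
#' @param pop_size,generations Optimizer size.
#' @param replicates Replicate landscapes per evaluation (full scale: 12).
#' @param base_dist Area distribution used on the uncertainty axis.
#' @param base_model Uncertainty model used on the area axis.
#' @param seed Base seed; level `i` uses `derive_seed(seed, i)`.
#' @param ... Further arguments passed to [optimize_regimes()].
#' @return An `fs_sweep` object: list with `runs` (one `fs_regime_opt` per
#'   level, each carrying its `level`), `axis`, `levels`.
#' @export
run_sweep <- function(axis = c("landholding_area", "uncertainty"),
                      levels = NULL, n_rows = 30, n_cols = 30, pool_size = 12,
                      k = 3, pop_size = 12, generations = 5, replicates = 2,
                      base_dist = area_distribution(),
                      base_model = uncertainty_model(), seed = 1, ...) {
  axis <- match.arg(axis)
  levels <- levels %||% sweep_levels(axis)
  if (length(levels) == 0) abort("`levels` must be non-empty.")
  runs <- purrr::map(seq_along(levels), function(i) {
    lv <- if (is.list(levels)) levels[[i]] else levels[i]
    level_seed <- derive_seed(seed, i)
    if (axis == "landholding_area") {
      dist <- area_distribution(lv[1], lv[2])
      model <- base_model
    } else {
      dist <- base_dist
      model <- uncertainty_from_max_variance(lv)
    }
    pool <- generate_pool(pool_size, n_rows, n_cols, dist,
                          seed = derive_seed(level_seed, 11))
    res <- optimize_regimes(pool, k = k, pop_size = pop_size,
                            generations = generations, replicates = replicates,
                            model = model, seed = derive_seed(level_seed, 13), ...)
    res$level <- lv
    res$axis <- axis
    res
  })
  structure(list(runs = runs, axis = axis, levels = levels, seed = seed),
            class = "fs_sweep")
}

#' @export
print.fs_sweep <- function(x, ...) {
  cat(sprintf("<fs_sweep> axis '%s', %d levels\n", x$axis, length(x$runs)))
  invisible(x)
}

#' Compare sweep runs within a restriction scenario
#'
#' Filters each level's frontier by the scenario, pools the surviving regimes
#' across levels, computes the pairwise density-intersection distances between
#' them, and embeds the distance matrix with principal coordinates - the basis
#' of the per-scenario comparison panels. With fewer than two pooled solutions
#' the embedding is skipped and reported as such.
#'
#' @param sweep An [run_sweep()] result, or a plain list of `fs_regime_opt`
#'   runs each carrying a `level`.
#' @param scen A [scenario()] (default `"none"`).
#' @param bandwidth Kernel bandwidth for [solution_density()] (default 5).
#' @return A list: `solutions` (tibble with `level` and the filtered frontier
#'   rows), `distance_matrix`, `pcoa` (`NULL` when skipped), `n`, `skipped`.
#' @export
compare_runs <- function(sweep, scen = scenario("none"), bandwidth = 5) {
  runs <- if (inherits(sweep, "fs_sweep")) sweep$runs else sweep
  if (length(runs) < 2) abort("`sweep` must contain at least two levels.")
  pooled <- purrr::map_dfr(runs, function(r) {
    f <- apply_scenario(r$frontier, scen)
    if (nrow(f) > 0) f$level <- paste(r$level, collapse = "/")
    f
  })
  n <- nrow(pooled)
  if (n < 2) {
    return(list(solutions = pooled, distance_matrix = NULL, pcoa = NULL,
                n = n, skipped = TRUE))
  }
  D <- density_distance_matrix(pooled$regime, bandwidth = bandwidth)
  emb <- pcoa(D)
  list(solutions = pooled, distance_matrix = D, pcoa = emb, n = n,
       skipped = FALSE)
}
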
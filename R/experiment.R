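# Known configuration keys with their validators.
config_schema <- function() {
  pos_int <- function(x) is.numeric(x) && length(x) == 1 && x >= 1 && x == floor(x)
  prob <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  pos_num <- function(x) is.numeric(x) && length(x) == 1 && x > 0
  list(
    preset = function(x) is.character(x) && x %in% c("desk", "full", "custom"),
    n_rows = pos_int, n_cols = pos_int, pool_size = pos_int,
    area_mean = pos_num, area_variance = pos_num,
    uncertainty_shape = pos_num,
    horizon = pos_int, burn_in = function(x) is.numeric(x) && x >= 0,
    replicates = pos_int, pop_size = pos_int, generations = pos_int,
    cx_prob = prob, mut_prob = prob,
    eta_cx = pos_num, eta_mut = pos_num,
    strategies = function(x) is.numeric(x) && all(x >= 1) && all(x <= 5),
    min_interval = function(x) is.numeric(x) && length(x) == 1 && x >= 3,
    max_interval = function(x) is.numeric(x) && length(x) == 1 && x <= 100,
    bandwidth = pos_num, b_max = pos_num, rate = pos_num,
    hv_samples = pos_int, seed = function(x) is.numeric(x) && length(x) == 1
  )
}

#' Experiment configuration
#'
#' `default_config()` returns the full-scale configuration: 180 x 180-cell
#' landscapes, pool of 2000, Gamma(mean 20, variance 100) holding areas,
#' uncertainty shape 100, 100-year horizon with 20-year burn-in, population
#' 800, 400 generations, 24 replicates per evaluation, crossover 0.7 and
#' mutation 0.2, interval bounds 3-100 years, density bandwidth 5.
#' `preset_config("desk")` is the scaled-down preset used for tests and quick
#' runs (30 x 30 cells, pool 20, population 40, 30 generations, 4 replicates,
#' three-group strategy).
#'
#' @param preset `"full"` (full scale) or `"desk"`.
#' @return A named list of configuration values (class `fs_config`).
#' @export
default_config <- function() {
  structure(list(
    preset = "full",
    n_rows = 180L, n_cols = 180L, pool_size = 2000L,
    area_mean = 20, area_variance = 100,
    uncertainty_shape = 100,
    horizon = 100L, burn_in = 20L,
    replicates = 24L, pop_size = 800L, generations = 400L,
    cx_prob = 0.7, mut_prob = 0.2, eta_cx = 5, eta_mut = 10,
    strategies = 1:5,
    min_interval = 3, max_interval = 100,
    bandwidth = 5, b_max = 20000, rate = 0.06,
    hv_samples = 100000L, seed = 1L
  ), class = "fs_config")
}

#' @rdname default_config
#' @export
preset_config <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  cfg <- default_config()
  if (preset == "desk") {
    cfg[c("n_rows", "n_cols", "pool_size", "replicates",
          "pop_size", "generations", "strategies", "hv_samples")] <-
      list(30L, 30L, 20L, 4L, 40L, 30L, 3L, 20000L)
  }
  cfg$preset <- preset
  cfg
}

#' Validate a configuration
#'
#' Checks every key against the schema (unknown keys and schema violations are
#' rejected with the offending key named) plus cross-field constraints:
#' burn-in below the horizon, even population, interval bounds within
#' \[3, 100\], pool at least as large as the replicate count.
#'
#' @param config A configuration list.
#' @return The validated config (class `fs_config`), invisibly usable onward.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in names(config)) {
    if (!schema[[key]](config[[key]])) {
      abort(sprintf("Configuration key `%s` has an invalid value.", key))
    }
  }
  if (config$burn_in >= config$horizon) abort("`burn_in` must be below `horizon`.")
  if (config$pop_size %% 2 != 0) abort("`pop_size` must be even.")
  if (config$min_interval >= config$max_interval) {
    abort("`min_interval` must be below `max_interval`.")
  }
  if (config$pool_size < config$replicates) {
    abort("`pool_size` must be at least `replicates`.")
  }
  structure(config, class = "fs_config")
}

#' Load / save experiment configuration (YAML)
#'
#' `load_config()` reads a flat key-value YAML file, fills unspecified keys
#' with the defaults of the file's `preset` (or the full-scale defaults), and
#' validates; unknown keys are rejected with a message naming the key.
#' `save_config()` writes a config so that load/save round-trips losslessly.
#'
#' @param path YAML file path.
#' @return `load_config()`: a validated `fs_config`; `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  user <- yaml::read_yaml(path) %||% list()
  base <- if (!is.null(user$preset) && user$preset == "desk") {
    preset_config("desk")
  } else {
    default_config()
  }
  unknown <- setdiff(names(user), names(config_schema()))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(unclass(base), user)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable hash of a configuration, stamped on every output.
config_hash <- function(config) rlang::hash(unclass(config))

#' Run a full simulation-optimization experiment
#'
#' End-to-end pipeline: generate the landscape pool, run one NSGA-II
#' optimization per strategy in `config$strategies`, and write everything to
#' `out_dir`: per-strategy frontier CSVs, hypervolume-series CSVs, a pooled
#' frontier with level-diagram scores, and a `run.json` metadata file stamped
#' with the configuration, its hash and the seeds. A failure partway leaves an
#' `error.json` manifest describing the failed stage.
#'
#' @param config A validated configuration (see [default_config()],
#'   [preset_config()], [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the per-strategy results, the pooled
#'   frontier and the output paths.
#' @export
run_experiment <- function(config, out_dir, quiet = TRUE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "pool"
  result <- tryCatch({
    say("Generating pool of %d landscapes...", config$pool_size)
    dist <- area_distribution(config$area_mean, config$area_variance)
    model <- uncertainty_model(config$uncertainty_shape)
    curve <- biomass_curve(config$b_max, config$rate)
    pool <- generate_pool(config$pool_size, config$n_rows, config$n_cols,
                          dist, seed = derive_seed(config$seed, 2))
    stage <- "optimize"
    runs <- list()
    for (k in config$strategies) {
      say("Optimizing strategy k = %d...", k)
      run <- optimize_regimes(
        pool, k = k, pop_size = config$pop_size,
        generations = config$generations, replicates = config$replicates,
        model = model, horizon = config$horizon, burn_in = config$burn_in,
        curve = curve, seed = derive_seed(config$seed, 100 + k),
        cx_prob = config$cx_prob, mut_prob = config$mut_prob,
        eta_cx = config$eta_cx, eta_mut = config$eta_mut,
        hv_samples = config$hv_samples)
      runs[[as.character(k)]] <- run
      write_frontier(run$frontier,
                     file.path(out_dir, sprintf("frontier_k%d.csv", k)))
      utils::write.csv(run$hypervolume,
                       file.path(out_dir, sprintf("hypervolume_k%d.csv", k)),
                       row.names = FALSE)
    }
    stage <- "postprocess"
    pooled <- combine_frontiers(runs)
    scored <- level_scores(pooled)
    write_frontier(scored[, setdiff(names(scored), paste0("z_", obj_names()))],
                   file.path(out_dir, "frontier_pooled.csv"))
    stage <- "metadata"
    meta <- list(config = unclass(config), config_hash = config_hash(config),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 n_strategies = length(runs),
                 frontier_sizes = vapply(runs, function(r) length(r$front), 0L))
    jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
    list(runs = runs, frontier = scored, out_dir = out_dir)
  }, error = function(e) {
    jsonlite::write_json(
      list(error = conditionMessage(e), stage = stage,
           config_hash = config_hash(config)),
      file.path(out_dir, "error.json"), auto_unbox = TRUE)
    abort(sprintf("Experiment failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}

#' Deterministic test fixtures
#'
#' Small objects used by the test-suite and examples: 5x5 and 10x10 random
#' landscapes, a 20-point random 6-objective set with its Pareto ranks, and
#' hand-enumerated surface-metric cases with their expected values.
#'
#' @param seed Integer seed (default 1); identical seeds regenerate identical
#'   fixtures.
#' @return A list with `landscape_5x5`, `landscape_10x10`, `objective_set`
#'   (matrix), `ranks`, and `metric_cases`.
#' @export
make_fixtures <- function(seed = 1) {
  objective_set <- with_seed(derive_seed(seed, 3),
                             matrix(stats::runif(20 * 6), 20, 6))
  list(
    landscape_5x5 = hex_landscape(5, 5, seed = derive_seed(seed, 1)),
    landscape_10x10 = hex_landscape(10, 10, seed = derive_seed(seed, 2)),
    objective_set = objective_set,
    ranks = nondominated_sort(objective_set),
    metric_cases = list(
      # 3-cell path, biomass (0, 1, 4): |diffs| {1, 3}, population variance 1
      edge = list(b = c(0, 1, 4), pairs = cbind(c(1, 2), c(2, 3)), expected = 1),
      # population-moment skewness of (0, 0, 0, 1): m3/m2^1.5 = 2/sqrt(3)
      skew = list(b = c(0, 0, 0, 1), expected = (3 / 32) / (3 / 16)^1.5)
    )
  )
}
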
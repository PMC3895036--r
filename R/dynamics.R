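# Prescribed interval encoding "no management for the whole simulation".
NO_MANAGEMENT <- 100

#' Group-structured management regime
#'
#' A regime prescribes, for 1-5 groups of landowners, the interval in years
#' between consecutive understory clearings and the proportion of landowners in
#' each group. Intervals are bounded to \[3, 100\] years; 100 encodes absence of
#' management over the simulation period. Who belongs to which group is *not*
#' part of the rule: owners are allocated at random with the given proportions.
#'
#' @param intervals Numeric vector (length 1-5) of clearing intervals in years.
#' @param proportions Non-negative vector of the same length summing to 1
#'   (within 1e-9); defaults to equal shares.
#' @return A `management_regime` list with `intervals`, `proportions`,
#'   `n_groups`.
#' @export
#' @examples
#' # the compromise-type regime: 55% clearing every ~5 y, 35% at 75 y, 10% never
#' management_regime(c(5, 75, 100), c(0.55, 0.35, 0.10))
management_regime <- function(intervals, proportions = NULL) {
  k <- length(intervals)
  if (k < 1 || k > 5) abort("A regime must have between 1 and 5 groups.")
  if (any(!is.finite(intervals)) || any(intervals < 3) || any(intervals > 100)) {
    abort("Management intervals must lie in [3, 100] years (100 = no management).")
  }
  proportions <- proportions %||% rep(1 / k, k)
  if (length(proportions) != k || any(proportions < 0)) {
    abort("`proportions` must be non-negative and match `intervals` in length.")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1 (within 1e-9).")
  }
  structure(list(intervals = as.numeric(intervals),
                 proportions = as.numeric(proportions), n_groups = k),
            class = "management_regime")
}

#' @export
print.management_regime <- function(x, ...) {
  cat(sprintf("<management_regime> %d group(s)\n", x$n_groups))
  for (g in seq_len(x$n_groups)) {
    lab <- if (x$intervals[g] >= NO_MANAGEMENT) "no management" else
      sprintf("every %.3g y", x$intervals[g])
    cat(sprintf("  group %d: %4.1f%% of owners, %s\n", g, 100 * x$proportions[g], lab))
  }
  invisible(x)
}

#' Implementation-uncertainty model
#'
#' Landowners implement a prescribed clearing interval imperfectly: the
#' realized interval is Gamma distributed with mean equal to the prescribed
#' interval and a constant shape parameter, so variance = mean^2/shape grows
#' with the interval (uncertainty is larger at longer intervals). The base
#' model uses shape 100.
#'
#' `uncertainty_from_max_variance()` parameterizes the model by the variance at
#' the 100-year interval: shape = 100^2 / V.
#'
#' @param shape Positive Gamma shape (default 100).
#' @return An `uncertainty_model` list with `shape`.
#' @export
#' @examples
#' uncertainty_model()                 # base model, shape 100
#' uncertainty_from_max_variance(1000) # high uncertainty, shape 10
uncertainty_model <- function(shape = 100) {
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0) {
    abort("`shape` must be a positive number.")
  }
  structure(list(shape = shape), class = "uncertainty_model")
}

#' @rdname uncertainty_model
#' @param max_variance Variance (years^2) of the implemented interval at the
#'   100-year prescribed interval; must be positive.
#' @export
uncertainty_from_max_variance <- function(max_variance) {
  if (!is.numeric(max_variance) || length(max_variance) != 1 || max_variance <= 0) {
    abort("`max_variance` must be a positive number.")
  }
  uncertainty_model(shape = NO_MANAGEMENT^2 / max_variance)
}

#' @export
print.uncertainty_model <- function(x, ...) {
  cat(sprintf("<uncertainty_model> Gamma shape %g (variance at 100 y: %g y^2)\n",
              x$shape, NO_MANAGEMENT^2 / x$shape))
  invisible(x)
}

#' Sample implemented clearing intervals
#'
#' Draws realized intervals for a prescribed interval under an
#' [uncertainty_model()]: Gamma with mean `prescribed` and variance
#' `prescribed^2 / shape`. A prescribed interval of 100 (no management) never
#' reaches this call in the simulator.
#'
#' @param prescribed Prescribed interval(s) in years, in \[3, 100).
#' @param model An [uncertainty_model()].
#' @param n Number of draws (default `length(prescribed)`; `prescribed` is
#'   recycled).
#' @param seed Optional integer seed.
#' @return Numeric vector of positive realized intervals.
#' @export
#' @examples
#' summary(sample_interval(50, n = 1000, seed = 1)) # mean ~50, sd ~5
sample_interval <- function(prescribed, model = uncertainty_model(),
                            n = length(prescribed), seed = NULL) {
  stopifnot(inherits(model, "uncertainty_model"))
  if (any(prescribed < 3) || any(prescribed >= NO_MANAGEMENT)) {
    abort("`prescribed` must lie in [3, 100); 100 encodes no management and is never sampled.")
  }
  with_seed(seed, stats::rgamma(n, shape = model$shape,
                                scale = prescribed / model$shape))
}

#' Understory biomass accumulation curve
#'
#' After a clearing event the understory regrows towards an asymptote; fine
#' fuels and leaves accumulate following a monomolecular curve
#' B(a) = b_max (1 - exp(-rate * a)). With the defaults (b_max = 20000 kg/ha,
#' rate = 0.06 / y) the stand reaches ~95% of the plateau by age 50, so
#' variation beyond 50 years is slight. All optimization objectives are
#' invariant to `b_max` (they are either normalized, ratios of moments, or
#' age-class areas), so the absolute scale is conventional.
#'
#' @param b_max Asymptotic biomass (kg/ha).
#' @param rate Accumulation rate (1/years).
#' @return A `biomass_curve` list.
#' @export
biomass_curve <- function(b_max = 20000, rate = 0.06) {
  if (b_max <= 0 || rate <= 0) abort("`b_max` and `rate` must be positive.")
  structure(list(b_max = b_max, rate = rate), class = "biomass_curve")
}

#' @rdname biomass_curve
#' @param age Stand age(s) in years since last clearing (>= 0).
#' @param curve A [biomass_curve()].
#' @return `biomass()`: biomass in kg/ha, 0 at age 0, non-decreasing in age.
#' @export
#' @examples
#' biomass(c(0, 10, 50, 70))
biomass <- function(age, curve = biomass_curve()) {
  stopifnot(inherits(curve, "biomass_curve"))
  if (any(age < 0)) abort("`age` must be non-negative.")
  curve$b_max * (1 - exp(-curve$rate * age))
}

#' Allocate landowners to management groups
#'
#' Each owner is independently assigned to group g with probability equal to
#' that group's proportion (a per-owner multinomial draw): the rule controls
#' proportions of landowners, not who complies with which interval.
#'
#' @param owners Vector of owner ids (may be empty).
#' @param regime A [management_regime()].
#' @param seed Optional integer seed.
#' @return Integer vector of group indices (1-based), named by owner.
#' @export
allocate_owners <- function(owners, regime, seed = NULL) {
  stopifnot(inherits(regime, "management_regime"))
  if (length(owners) == 0) return(stats::setNames(integer(0), character(0)))
  with_seed(seed, {
    g <- sample.int(regime$n_groups, length(owners), replace = TRUE,
                    prob = regime$proportions)
    stats::setNames(as.integer(g), owners)
  })
}

#' Simulate yearly landscape dynamics under a management regime
#'
#' Runs the disturbance-succession loop for `horizon` years. Each year, owners
#' whose clearing is due clear their whole landholding (ages reset to 0; a
#' landholding is always managed at once), the per-year landscape summaries are
#' recorded, and every cell then ages one year. Clearing starts at time zero
#' for holdings whose initial understory age is at least the prescribed
#' interval; otherwise at the year the age first reaches the holding's sampled
#' (realized) interval. After each clearing the next due time advances by a
#' fresh draw from [sample_interval()], so implementation uncertainty applies
#' to every event independently. Owners in a 100-year group never clear.
#'
#' @param landscape A [hex_landscape()].
#' @param regime A [management_regime()].
#' @param allocation Optional owner-to-group assignment as produced by
#'   [allocate_owners()]; drawn internally when `NULL`.
#' @param model An [uncertainty_model()].
#' @param horizon Simulation length in years (default 100).
#' @param curve A [biomass_curve()].
#' @param seed Optional integer seed (allocation + interval draws).
#' @param keep_history Also record per-owner state: attributes `age_history`
#'   and `cleared_history` (year-by-owner matrices, ages as recorded each
#'   year), `owners` and `owner_sizes`. Off by default (memory).
#' @return A `fs_trajectory` tibble with one row per year (`year` = 0 ...
#'   horizon-1) and columns `mean_biomass` (kg/ha), `edge_contrast` ((kg/ha)^2),
#'   `skewness`, `pct_young` (% area aged < 10 y), `pct_mid` (% aged 30-60),
#'   `pct_late` (% aged > 60), `pct_managed` (% of area cleared that year).
#' @export
#' @examples
#' l <- hex_landscape(8, 8, seed = 1)
#' r <- management_regime(c(5, 75, 100), c(0.55, 0.35, 0.10))
#' simulate_landscape(l, r, horizon = 30, seed = 2)
simulate_landscape <- function(landscape, regime, allocation = NULL,
                               model = uncertainty_model(), horizon = 100,
                               curve = biomass_curve(), seed = NULL,
                               keep_history = FALSE) {
  stopifnot(inherits(landscape, "hex_landscape"),
            inherits(regime, "management_regime"),
            inherits(model, "uncertainty_model"))
  if (horizon < 1) abort("`horizon` must be at least 1 year.")
  grid <- landscape_grid(landscape)
  with_seed(seed, {
    owners <- sort(unique(landscape$owner))
    n_own <- length(owners)
    oi_cell <- match(landscape$owner, owners)        # per-cell owner index
    size <- tabulate(oi_cell, nbins = n_own)         # cells (= ha) per owner
    n <- grid$n_cells
    po_i <- oi_cell[grid$pairs[, 1]]                 # pair owner indices
    po_j <- oi_cell[grid$pairs[, 2]]

    if (is.null(allocation)) {
      group <- unname(allocate_owners(owners, regime))
    } else {
      group <- unname(allocation[as.character(owners)])
      if (anyNA(group)) abort("`allocation` must cover every owner in the landscape.")
    }
    prescribed <- regime$intervals[group]
    managed <- prescribed < NO_MANAGEMENT

    age <- as.numeric(landscape$age[match(owners, landscape$owner)])
    next_due <- rep(Inf, n_own)
    start_now <- managed & age >= prescribed
    next_due[start_now] <- 0
    later <- managed & !start_now
    if (any(later)) {
      next_due[later] <- sample_interval(prescribed[later], model) - age[later]
    }

    yrs <- seq_len(horizon) - 1L
    if (keep_history) {
      age_hist <- matrix(NA_real_, horizon, n_own)
      clr_hist <- matrix(FALSE, horizon, n_own)
    }
    out <- matrix(NA_real_, horizon, 7,
                  dimnames = list(NULL, c("mean_biomass", "edge_contrast",
                                          "skewness", "pct_young", "pct_mid",
                                          "pct_late", "pct_managed")))
    for (t in yrs) {
      due <- managed & next_due <= t
      if (any(due)) {
        age[due] <- 0
        next_due[due] <- next_due[due] + sample_interval(prescribed[due], model)
      }
      b_own <- biomass(age, curve)
      mu <- sum(b_own * size) / n
      d <- abs(b_own[po_i] - b_own[po_j])
      edge <- mean(d^2) - mean(d)^2
      m2 <- sum(size * (b_own - mu)^2) / n
      m3 <- sum(size * (b_own - mu)^3) / n
      skw <- if (m2 > 0) m3 / m2^1.5 else 0
      out[t + 1L, ] <- c(
        mu, edge, skw,
        100 * sum(size[age < 10]) / n,
        100 * sum(size[age >= 30 & age <= 60]) / n,
        100 * sum(size[age >= 61]) / n,
        100 * sum(size[due]) / n
      )
      if (keep_history) {
        age_hist[t + 1L, ] <- age
        clr_hist[t + 1L, ] <- due
      }
      age <- age + 1
    }
    tr <- structure(
      tibble(year = yrs, as_tibble(out)),
      class = c("fs_trajectory", class(tibble())),
      horizon = horizon, regime = regime,
      landscape_id = attr(landscape, "landscape_id")
    )
    if (keep_history) {
      attr(tr, "age_history") <- age_hist
      attr(tr, "cleared_history") <- clr_hist
      attr(tr, "owners") <- owners
      attr(tr, "owner_sizes") <- size
    }
    tr
  })
}

#' Managed fraction of the landscape in a given year
#'
#' @param trajectory A [simulate_landscape()] result.
#' @param year Year index, 0-based, within the simulated horizon.
#' @return Percentage of landscape area cleared in that year.
#' @export
managed_fraction <- function(trajectory, year) {
  stopifnot(inherits(trajectory, "fs_trajectory"))
  if (length(year) != 1 || year < 0 || year >= attr(trajectory, "horizon")) {
    abort("`year` must lie in [0, horizon).")
  }
  trajectory$pct_managed[trajectory$year == year]
}

#' Export a trajectory as CSV
#'
#' Columns `year, mean_biomass_kg_ha, edge_contrast, skewness, pct_age_30_60,
#' pct_age_gt60, pct_managed` (plus `pct_age_lt10`).
#'
#' @param trajectory A `fs_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "fs_trajectory"))
  out <- tibble(year = trajectory$year,
                mean_biomass_kg_ha = trajectory$mean_biomass,
                edge_contrast = trajectory$edge_contrast,
                skewness = trajectory$skewness,
                pct_age_lt10 = trajectory$pct_young,
                pct_age_30_60 = trajectory$pct_mid,
                pct_age_gt60 = trajectory$pct_late,
                pct_managed = trajectory$pct_managed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
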
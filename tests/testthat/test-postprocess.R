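test_that("level-diagram distances follow the 6/3/2 weighting", {
  best <- tibble::tibble(cost = 0, fuel_load = 100, edge_contrast = 10,
                         skewness = 1, mid_area = 30, late_area = 30)
  worst <- tibble::tibble(cost = 20, fuel_load = 900, edge_contrast = 1,
                          skewness = -1, mid_area = 5, late_area = 2)
  scored <- level_scores(dplyr::bind_rows(best, worst))
  expect_equal(scored$distance_to_ideal[1], 0)
  expect_equal(scored$distance_to_ideal[2], sqrt(66)) # worst in everything

  # worst only in cost: the single 6-weighted term
  mixed <- dplyr::bind_rows(
    tibble::tibble(cost = 10, fuel_load = 100, edge_contrast = 10,
                   skewness = 1, mid_area = 30, late_area = 30),
    tibble::tibble(cost = 0, fuel_load = 900, edge_contrast = 1,
                   skewness = -1, mid_area = 5, late_area = 2))
  sm <- level_scores(mixed)
  expect_equal(sm$distance_to_ideal[1], 6)
  expect_equal(sm$distance_to_ideal[2], sqrt(66 - 36))

  # standardization absorbs affine rescaling of any raw objective
  f <- random_frontier(12, seed = 31)
  f2 <- f
  f2$fuel_load <- 3.7 * f2$fuel_load + 1000
  expect_equal(level_scores(f)$distance_to_ideal,
               level_scores(f2)$distance_to_ideal)

  # single solution: degenerate, all-zero distance
  expect_equal(level_scores(f[1, ])$distance_to_ideal, 0)
})

test_that("level-diagram long data carries one row per solution x objective", {
  f <- random_frontier(5, seed = 32)
  long <- level_diagram_data(f)
  expect_equal(nrow(long), 30)
  expect_true(all(long$standardized >= 0 & long$standardized <= 1))
  per_sol <- tapply(long$distance_to_ideal, long$solution,
                    function(x) length(unique(x)))
  expect_true(all(per_sol == 1))
})

test_that("restriction scenarios filter exactly as specified", {
  f <- random_frontier(40, seed = 33)
  f$cost[1] <- 5.375; f$cost[2] <- 5.5
  kept <- apply_scenario(f, scenario("cost5"))
  expect_true(1 %in% which(f$cost %in% kept$cost & f$fuel_load %in% kept$fuel_load))
  expect_true(all(abs(kept$cost - 5) <= 0.375))
  expect_false(5.5 %in% kept$cost)

  f$mid_area[3] <- 9.9; f$late_area[3] <- 9.9
  f$mid_area[4] <- 9.8; f$late_area[4] <- 50
  bio <- apply_scenario(f, scenario("biodiversity"))
  expect_true(all(bio$mid_area >= 9.9 & bio$late_area >= 9.9))
  expect_true(any(abs(bio$mid_area - 9.9) < 1e-12))
  expect_false(9.8 %in% bio$mid_area)

  fire <- apply_scenario(f, scenario("fire"))
  expect_true(all(fire$fuel_load <= quantile(f$fuel_load, 0.25)))
  expect_true(all(fire$edge_contrast >= quantile(f$edge_contrast, 0.75)))

  expect_equal(nrow(apply_scenario(f[0, ], scenario("cost10"))), 0)

  # monotonicity: the compromise scenario is a refinement of its cost part
  comp <- apply_scenario(f, scenario("compromise"))
  cost_only <- new_scenario("c", list(
    scenario_constraint("cost", "threshold", op = "<=", value = 20)))
  expect_true(nrow(comp) <= nrow(apply_scenario(f, cost_only)))
  expect_true(all(comp$cost <= 20 & comp$mid_area >= 9 & comp$late_area >= 9))

  expect_error(new_scenario("bad", list(
    scenario_constraint("not_an_objective", "threshold", op = "<=", value = 1))),
    "objectives")
})

test_that("regime re-simulation summarizes per-year dynamics", {
  none <- management_regime(100)
  rs <- compromise_rescan(none, n_sims = 2, n_rows = 6, n_cols = 6,
                          horizon = 25, seed = 70)
  managed <- rs[rs$variable == "pct_managed", ]
  expect_equal(nrow(managed), 25)
  expect_true(all(managed$mean == 0))

  one <- compromise_rescan(management_regime(c(10, 100), c(0.5, 0.5)),
                           n_sims = 1, n_rows = 6, n_cols = 6,
                           horizon = 15, seed = 71)
  expect_true(all(one$sd == 0)) # single simulation: no spread
})

test_that("long-run age composition matches the renewal-theory mixture", {
  # fraction of time with age < a is min(a/m, 1) per group, mixed by proportion
  regime <- management_regime(c(5, 75, 100), c(0.55, 0.35, 0.10))
  rs <- compromise_rescan(regime, n_sims = 5, n_rows = 30, n_cols = 30,
                          horizon = 100, seed = 72)
  young <- rs[rs$variable == "pct_young" & rs$year >= 20, ]
  expected <- 100 * (0.55 * 1 + 0.35 * (10 / 75) + 0.10 * 0)
  expect_lt(abs(mean(young$mean) - expected), 6)
})

test_that("solution densities are normalized Gaussian mixtures", {
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  for (r in list(management_regime(3), management_regime(100),
                 management_regime(c(5, 75, 100), c(0.55, 0.35, 0.10)))) {
    d <- solution_density(r)
    expect_lt(abs(trapz(d$x, d$density) - 1), 1e-3)
  }
  single <- solution_density(management_regime(40))
  expect_equal(single$x[which.max(single$density)], 40)

  # mirrored regimes about the grid midpoint give mirrored densities
  a <- solution_density(management_regime(c(20, 80), c(0.3, 0.7)))
  b <- solution_density(management_regime(c(103 - 20, 103 - 80), c(0.3, 0.7)))
  expect_equal(a$density, rev(b$density), tolerance = 1e-12)
})

test_that("density distance is a bounded symmetric dissimilarity", {
  r1 <- management_regime(c(5, 75), c(0.5, 0.5))
  r2 <- management_regime(c(30, 90), c(0.2, 0.8))
  d1 <- solution_density(r1); d2 <- solution_density(r2)
  expect_equal(density_distance(d1, d1), 0, tolerance = 1e-3) # grid-tail only
  expect_equal(density_distance(d1, d2), density_distance(d2, d1))
  expect_true(density_distance(d1, d2) > 0 && density_distance(d1, d2) <= 1)

  far <- density_distance(solution_density(management_regime(3)),
                          solution_density(management_regime(100)))
  expect_gte(far, 0.99) # Gaussians 97 years apart at sd 5: negligible overlap

  short <- solution_density(r1, grid = seq(0, 100, 0.5))
  expect_error(density_distance(d1, short), "same grid")

  D <- density_distance_matrix(list(r1, r2, management_regime(50)))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
})

test_that("principal coordinates recover Euclidean configurations", {
  set.seed(34)
  pts <- cbind(runif(5), runif(5))
  D <- as.matrix(dist(pts))
  emb <- pcoa(D)
  rec <- as.matrix(dist(emb$all_coordinates))
  expect_equal(rec, D, tolerance = 1e-8, ignore_attr = TRUE) # exact recovery
  expect_false(emb$degenerate)
  expect_true(all(diff(emb$eigenvalues[1:2]) <= 0))

  # brute-force double-centering oracle on a 4x4 matrix
  D4 <- as.matrix(dist(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  o <- oracle_pcoa(D4)
  e4 <- pcoa(D4)
  expect_equal(as.matrix(dist(e4$all_coordinates)),
               as.matrix(dist(o$coordinates)), tolerance = 1e-8)
  expect_equal(sort(e4$eigenvalues, decreasing = TRUE)[1:2],
               sort(o$eigenvalues, decreasing = TRUE)[1:2], tolerance = 1e-8)

  # non-Euclidean input: negative eigenvalues dropped from the denominator
  Dn <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 1,
                 1, 1, 1, 0), 4, 4) * c(1)
  Dn[1, 2] <- Dn[2, 1] <- 2.05 # violates triangle-ish embedding
  en <- pcoa(Dn)
  pos <- en$eigenvalues[en$eigenvalues > 1e-12]
  expect_equal(sum(en$variance_explained[1:2] > 0), 2)
  expect_lte(sum(en$variance_explained, na.rm = TRUE), 1 + 1e-9)
  expect_equal(en$variance_explained[1], en$eigenvalues[1] / sum(pos))

  expect_error(pcoa(matrix(1:6, 2, 3)), "square")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})
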
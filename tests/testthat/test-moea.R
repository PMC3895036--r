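test_that("Pareto dominance follows the componentwise definition", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(2, 2), c(1, 1)))
  expect_false(dominates(c(1, 2), c(1, 2)))  # identical: neither way
  expect_false(dominates(c(1, 3), c(2, 2)))  # incomparable
  expect_false(dominates(c(2, 2), c(1, 3)))
  expect_true(dominates(c(1, 2), c(1, 3)))   # weak improvement suffices
})

test_that("nondominated sorting matches the iterative-removal oracle", {
  expect_equal(nondominated_sort(rbind(c(1, 2))), 1L)
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(nondominated_sort(chain), 1:3)

  set.seed(7)
  m20 <- matrix(runif(20 * 6), 20, 6)
  expect_equal(nondominated_sort(m20), oracle_sort(m20))
  for (n in c(5, 17, 50)) {
    m <- matrix(runif(n * 3), n, 3)
    expect_equal(nondominated_sort(m), oracle_sort(m))
  }
  # duplicated points land in the same rank
  dup <- rbind(c(1, 1), c(1, 1), c(2, 2))
  expect_equal(nondominated_sort(dup), c(1L, 1L, 2L))
})

test_that("crowding distance matches hand computation and the oracle", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  three <- rbind(c(0, 2), c(1, 1), c(2, 0)) # collinear, equally spaced
  expect_equal(crowding_distance(three), c(Inf, 2, Inf))
  # a zero-range objective contributes nothing
  flat <- rbind(c(0, 5), c(1, 5), c(2, 5), c(4, 5))
  expect_equal(crowding_distance(flat), c(Inf, 2 / 4, 3 / 4, Inf))

  set.seed(8)
  for (n in c(4, 9, 30)) {
    m <- matrix(runif(n * 4), n, 4)
    m <- m[nondominated_sort(m) == 1, , drop = FALSE]
    expect_equal(crowding_distance(m), oracle_crowding(m))
  }
})

test_that("hypervolume agrees with rectangle and union-of-boxes oracles", {
  expect_equal(hypervolume(rbind(c(1, 1)), ref = c(2, 2)), 1)
  front <- rbind(c(1, 3), c(2, 2), c(3, 1))
  hv0 <- hypervolume(front, ref = c(4, 4))
  expect_equal(hv0, oracle_hv_boxes(front, c(4, 4)))
  # adding a dominated point changes nothing
  expect_equal(hypervolume(rbind(front, c(3, 3)), ref = c(4, 4)), hv0)

  set.seed(9)
  pts <- matrix(runif(9), 3, 3)
  exact <- oracle_hv_boxes(pts, rep(1.5, 3))
  mc <- hypervolume(pts, ref = rep(1.5, 3), n_samples = 1e5, seed = 2,
                    method = "mc")
  expect_lt(abs(mc - exact) / exact, 0.02)

  expect_error(hypervolume(rbind(c(3, 1)), ref = c(2, 2)), "reference box")
})

test_that("genotype decoding clips, normalizes and falls back safely", {
  r1 <- decode_genotype(c(50, 0.4), k = 1)
  expect_equal(r1$proportions, 1)
  r2 <- decode_genotype(c(10, 60, 1, 1), k = 2)
  expect_equal(r2$proportions, c(0.5, 0.5))
  r3 <- decode_genotype(c(101, 60, 1, 1), k = 2)
  expect_equal(r3$intervals[1], 100)     # clipped to no-management
  r4 <- decode_genotype(c(10, 60, 0, 0), k = 2)
  expect_equal(r4$proportions, c(0.5, 0.5)) # all-zero weights: uniform
  r5 <- decode_genotype(c(10, 60, 90, 1, 0, 0), k = 3)
  expect_equal(r5$proportions, c(1, 0, 0))  # zero groups survive decoding
  expect_error(decode_genotype(c(1, 2, 3), k = 2), "length")
})

test_that("genotype evaluation is deterministic and reduces to one simulation", {
  pool <- generate_pool(4, 8, 8, seed = 50)
  x <- c(8, 70, 100, 0.5, 0.3, 0.2)
  o1 <- evaluate_genotype(x, 3, pool, replicates = 2, horizon = 40, seed = 51)
  o2 <- evaluate_genotype(x, 3, pool, replicates = 2, horizon = 40, seed = 51)
  expect_identical(o1, o2)

  # replicates = 1 equals a single allocate+simulate+summarize run
  o <- evaluate_genotype(x, 3, pool, replicates = 1, horizon = 40, seed = 52)
  set.seed(52)
  idx <- sample.int(4, 1)
  tr <- simulate_landscape(pool[[idx]], decode_genotype(x, 3), horizon = 40)
  expect_equal(o, objectives_from_trajectory(tr, burn_in = 20))

  expect_error(evaluate_genotype(x, 3, pool, replicates = 10), "at least")
})

test_that("the engine solves a biobjective problem with a known Pareto set", {
  # minimize (x^2, (x - 2)^2) on [0, 4]: Pareto-optimal x in [0, 2]
  fn <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  res <- nsga2(fn, lower = 0, upper = 4, n_obj = 2,
               pop_size = 40, generations = 50, seed = 12)
  expect_equal(nrow(res$genotypes), 40)        # population size constant
  xs <- res$genotypes[res$front, 1]
  expect_true(all(xs >= -1e-9 & xs <= 2 + 0.05))
  # final front mutually nondominated
  expect_true(all(nondominated_sort(res$objectives[res$front, , drop = FALSE]) == 1))
  # noise-free run: archive hypervolume series is non-decreasing
  expect_true(all(diff(res$hypervolume$hypervolume) >= -1e-12))
  # determinism
  res2 <- nsga2(fn, lower = 0, upper = 4, n_obj = 2,
                pop_size = 40, generations = 50, seed = 12)
  expect_identical(res$genotypes, res2$genotypes)
  expect_identical(res$hypervolume, res2$hypervolume)
})

test_that("variation operators respect bounds and probabilities", {
  set.seed(13)
  lower <- c(3, 3, 0, 0); upper <- c(100, 100, 1, 1)
  for (i in 1:20) {
    p1 <- runif(4, lower, upper); p2 <- runif(4, lower, upper)
    ch <- fuelscape:::sbx_pair(p1, p2, lower, upper)
    expect_true(all(ch[1, ] >= lower - 1e-9 & ch[1, ] <= upper + 1e-9))
    expect_true(all(ch[2, ] >= lower - 1e-9 & ch[2, ] <= upper + 1e-9))
    mu <- fuelscape:::poly_mutate(p1, lower, upper, prob = 1)
    expect_true(all(mu >= lower - 1e-9 & mu <= upper + 1e-9))
  }
  x <- runif(4, lower, upper)
  expect_identical(fuelscape:::poly_mutate(x, lower, upper, prob = 0), x)
})

test_that("regime optimization emits a valid, reproducible frontier", {
  pool <- generate_pool(4, 8, 8, seed = 60)
  res <- optimize_regimes(pool, k = 2, pop_size = 8, generations = 3,
                          replicates = 2, horizon = 30, seed = 61)
  expect_s3_class(res, "fs_regime_opt")
  f <- res$frontier
  expect_true(all(f$rank == 1))
  can <- objectives_canonical(f[, c("cost", "fuel_load", "edge_contrast",
                                    "skewness", "mid_area", "late_area")])
  expect_true(all(nondominated_sort(can) == 1))
  expect_true(all(vapply(f$regime, function(r) r$n_groups, 0L) == 2))

  res2 <- optimize_regimes(pool, k = 2, pop_size = 8, generations = 3,
                           replicates = 2, horizon = 30, seed = 61)
  expect_identical(res$objectives, res2$objectives)
  expect_identical(res$hypervolume, res2$hypervolume)

  pooled <- combine_frontiers(res, res2)
  expect_true(all(pooled$rank >= 1))
  expect_equal(nrow(pooled), nrow(res$frontier) + nrow(res2$frontier))

  path <- withr::local_tempfile(fileext = ".csv")
  write_frontier(f, path)
  out <- read.csv(path)
  expect_true(all(c("interval_1", "proportion_1", "cost", "rank") %in% names(out)))
})
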
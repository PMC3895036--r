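#' Pareto dominance in canonical minimization form
#'
#' `a` dominates `b` when `a` is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length (minimization form).
#' @return Logical.
#' @export
#' @examples
#' dominates(c(1, 1), c(2, 2)) # TRUE
#' dominates(c(1, 3), c(2, 2)) # FALSE (incomparable)
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

#' Fast nondominated sorting
#'
#' Assigns Pareto ranks: rank-1 solutions are nondominated; rank-2 solutions
#' are nondominated once rank 1 is removed, and so on.
#'
#' @param objectives Numeric matrix (rows = solutions) in canonical
#'   minimization form; at least one row.
#' @return Integer vector of ranks (1-based).
#' @export
nondominated_sort <- function(objectives) {
  m <- rbind(objectives)
  n <- nrow(m)
  if (n == 0) abort("`objectives` must contain at least one row.")
  if (n == 1) return(1L)
  k <- ncol(m)
  leq <- matrix(0L, n, n)
  for (j in seq_len(k)) {
    leq <- leq + outer(m[, j], m[, j], `<=`)
  }
  # dom[i, j]: i dominates j
  dom <- (leq == k) & (t(leq) < k)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    n_dominators <- colSums(dom[remaining, , drop = FALSE])
    front <- remaining & n_dominators == 0
    rank[front] <- r
    remaining <- remaining & !front
  }
  rank
}

#' Crowding distance within a Pareto front
#'
#' NSGA-II's diversity measure: for each objective the front is sorted and each
#' interior solution accumulates the gap between its neighbours, normalized by
#' the objective's range; boundary solutions get infinite distance. Objectives
#' with zero range contribute nothing. Fronts of one or two solutions are all
#' at infinity.
#'
#' @param front Numeric matrix of objective vectors of one front (canonical
#'   form); at least one row.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  m <- rbind(front)
  n <- nrow(m)
  if (n == 0) abort("`front` must contain at least one row.")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ord <- order(v)
    r <- v[ord[n]] - v[ord[1]]
    if (r > 0) {
      d[ord[c(1, n)]] <- Inf
      inner <- ord[2:(n - 1)]
      d[inner] <- d[inner] + (v[ord[3:n]] - v[ord[1:(n - 2)]]) / r
    }
  }
  d
}

# Ranks + crowding for a whole population (crowding computed per front).
rank_and_crowd <- function(objectives) {
  rank <- nondominated_sort(objectives)
  crowd <- numeric(length(rank))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(objectives[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowd)
}

#' Dominated hypervolume of a front
#'
#' Measure of the objective-space region dominated by a set of points and
#' bounded by a reference (worst) point, in canonical minimization form. In two
#' dimensions an exact sweep is used; in higher dimensions a Monte-Carlo
#' estimate with a fixed sample count and seed (exact computation is
#' exponential in the number of objectives).
#'
#' @param points Numeric matrix of objective vectors; every point must lie
#'   inside the box (componentwise `<= ref`).
#' @param ref Reference point (componentwise worst).
#' @param lower Lower corner of the sampling box for the Monte-Carlo method;
#'   defaults to the componentwise minimum of `points`.
#' @param n_samples Monte-Carlo sample count (default 1e5).
#' @param seed Seed for the Monte-Carlo sample (default 1).
#' @param method `"auto"` (exact in 2-D, Monte-Carlo otherwise), `"exact2d"`,
#'   or `"mc"`.
#' @return Dominated hypervolume (scalar).
#' @export
#' @examples
#' hypervolume(rbind(c(1, 1)), ref = c(2, 2)) # 1
hypervolume <- function(points, ref, lower = NULL, n_samples = 1e5, seed = 1,
                        method = c("auto", "exact2d", "mc")) {
  method <- match.arg(method)
  m <- rbind(points)
  if (any(sweep(m, 2, ref, `>`))) {
    abort("All points must lie inside the reference box (componentwise <= ref).")
  }
  if (method == "auto") method <- if (ncol(m) == 2) "exact2d" else "mc"
  if (method == "exact2d") {
    if (ncol(m) != 2) abort("`exact2d` requires two objectives.")
    keep <- nondominated_sort(m) == 1
    m <- m[keep, , drop = FALSE]
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    m <- m[!duplicated(m[, 1]), , drop = FALSE]
    prev_y <- ref[2]
    hv <- 0
    for (i in seq_len(nrow(m))) {
      hv <- hv + (ref[1] - m[i, 1]) * (prev_y - m[i, 2])
      prev_y <- m[i, 2]
    }
    return(hv)
  }
  lower <- lower %||% apply(m, 2, min)
  widths <- ref - lower
  if (any(widths <= 0)) return(0)
  with_seed(seed, {
    k <- ncol(m)
    s <- matrix(stats::runif(n_samples * k), n_samples, k)
    s <- sweep(sweep(s, 2, widths, `*`), 2, lower, `+`)
    dom <- rep(FALSE, n_samples)
    for (i in seq_len(nrow(m))) {
      nd <- which(!dom)
      if (length(nd) == 0) break
      ok <- rep(TRUE, length(nd))
      for (j in seq_len(k)) ok <- ok & (s[nd, j] >= m[i, j])
      dom[nd[ok]] <- TRUE
    }
    mean(dom) * prod(widths)
  })
}

#' Decode a genotype into a management regime
#'
#' A genotype carries `k` interval genes and `k` non-negative weight genes.
#' Interval genes are clipped to \[3, 100\] (100 = no management); proportions
#' are the weights normalized to sum 1 (an all-zero weight vector falls back to
#' uniform proportions). Zero-weight groups are representable, which is how the
#' effective number of groups can collapse below `k` during optimization.
#'
#' @param x Numeric genotype of length `2k`.
#' @param k Number of groups (1-5).
#' @return A [management_regime()].
#' @export
decode_genotype <- function(x, k) {
  if (length(x) != 2 * k) abort("`x` must have length 2 * k.")
  intervals <- pmin(pmax(x[seq_len(k)], 3), NO_MANAGEMENT)
  w <- pmax(x[k + seq_len(k)], 0)
  if (sum(w) == 0) w <- rep(1, k)
  management_regime(intervals, w / sum(w))
}

#' Evaluate a genotype on replicate landscapes
#'
#' The full evaluation protocol: decode the genotype, implement the regime
#' in `replicates` landscapes drawn from the pool without replacement (fresh
#' owner-group allocation per landscape), simulate `horizon` years, summarize
#' each trajectory into the six objectives, and aggregate with the
#' componentwise worst case ([aggregate_replicates()]).
#'
#' @param x Numeric genotype of length `2k`.
#' @param k Number of groups.
#' @param pool A [generate_pool()] result with at least `replicates` members.
#' @param replicates Number of replicate landscapes (full scale: 24; the
#'   sensitivity sweeps use 12).
#' @param model An [uncertainty_model()].
#' @param horizon,burn_in Simulation years and burn-in.
#' @param curve A [biomass_curve()].
#' @param seed Optional integer seed.
#' @return One-row display-form objective tibble.
#' @export
evaluate_genotype <- function(x, k, pool, replicates = 24,
                              model = uncertainty_model(), horizon = 100,
                              burn_in = 20, curve = biomass_curve(),
                              seed = NULL) {
  stopifnot(inherits(pool, "landscape_pool"))
  if (length(pool) < replicates) {
    abort("`pool` must contain at least `replicates` landscapes.")
  }
  regime <- decode_genotype(x, k)
  with_seed(seed, {
    idx <- sample.int(length(pool), replicates)
    reps <- purrr::map_dfr(idx, function(i) {
      tr <- simulate_landscape(pool[[i]], regime, model = model,
                               horizon = horizon, curve = curve)
      objectives_from_trajectory(tr, burn_in = burn_in)
    })
    aggregate_replicates(reps)
  })
}

# ---- variation operators (real-coded, bounded) ------------------------------

# Simulated binary crossover (SBX) on one parent pair. Applied per gene with
# probability 0.5 when the pair differs; children are clipped to bounds.
sbx_pair <- function(p1, p2, lower, upper, eta = 5) {
  c1 <- p1; c2 <- p2
  for (j in seq_along(p1)) {
    if (stats::runif(1) > 0.5) next
    y1 <- min(p1[j], p2[j]); y2 <- max(p1[j], p2[j])
    if (abs(y2 - y1) < 1e-14) next
    u <- stats::runif(1)
    beta <- 1 + 2 * (y1 - lower[j]) / (y2 - y1)
    alpha <- 2 - beta^(-(eta + 1))
    bq1 <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1)) else
      (1 / (2 - u * alpha))^(1 / (eta + 1))
    beta <- 1 + 2 * (upper[j] - y2) / (y2 - y1)
    alpha <- 2 - beta^(-(eta + 1))
    bq2 <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1)) else
      (1 / (2 - u * alpha))^(1 / (eta + 1))
    a <- 0.5 * ((y1 + y2) - bq1 * (y2 - y1))
    b <- 0.5 * ((y1 + y2) + bq2 * (y2 - y1))
    if (stats::runif(1) > 0.5) { tmp <- a; a <- b; b <- tmp }
    c1[j] <- min(max(a, lower[j]), upper[j])
    c2[j] <- min(max(b, lower[j]), upper[j])
  }
  rbind(c1, c2)
}

# Bounded polynomial mutation, applied per gene with probability `prob`.
poly_mutate <- function(x, lower, upper, eta = 10, prob = 0.2) {
  for (j in seq_along(x)) {
    if (stats::runif(1) > prob) next
    y <- x[j]; yl <- lower[j]; yu <- upper[j]
    if (yu <= yl) next
    u <- stats::runif(1)
    d1 <- (y - yl) / (yu - yl); d2 <- (yu - y) / (yu - yl)
    if (u < 0.5) {
      val <- 2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1)
      dq <- val^(1 / (eta + 1)) - 1
    } else {
      val <- 2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1)
      dq <- 1 - val^(1 / (eta + 1))
    }
    x[j] <- min(max(y + dq * (yu - yl), yl), yu)
  }
  x
}

# Binary tournament by crowded comparison: lower rank wins, ties broken by
# larger crowding distance, then by first index.
tournament_pick <- function(rank, crowd) {
  i <- sample.int(length(rank), 2, replace = TRUE)
  a <- i[1]; b <- i[2]
  if (rank[a] < rank[b]) return(a)
  if (rank[b] < rank[a]) return(b)
  if (crowd[a] >= crowd[b]) a else b
}

# ---- NSGA-II engine ---------------------------------------------------------

#' Elitist nondominated-sorting genetic algorithm (NSGA-II)
#'
#' Generic real-coded engine: binary-tournament parent selection by crowded
#' comparison, simulated binary crossover (probability `cx_prob`, distribution
#' index `eta_cx`), bounded polynomial mutation (per-gene probability
#' `mut_prob`, index `eta_mut`), and (mu + lambda) elitist survival by
#' (rank, crowding distance). Evaluated objective values are kept for the life
#' of an individual (no re-evaluation of survivors).
#'
#' Convergence is monitored with the hypervolume indicator computed on the
#' cumulative nondominated archive (every solution found so far), bounded by
#' the componentwise worst value attained in any generation; with a fixed
#' Monte-Carlo sample this series is non-decreasing by construction. The
#' per-generation population is what evolves; the archive is only a monitor.
#'
#' @param fn Vectorized objective function: takes a genotype matrix (rows =
#'   individuals) and returns a numeric matrix of canonical minimization
#'   objectives with one row per individual.
#' @param lower,upper Numeric bounds per gene.
#' @param n_obj Number of objectives.
#' @param pop_size Population size (even; full scale 800, desk preset 40).
#' @param generations Number of generations (full scale 400, desk preset 30).
#' @param cx_prob SBX probability per parent pair (default 0.7).
#' @param mut_prob Polynomial-mutation probability per gene (default 0.2).
#' @param eta_cx,eta_mut Distribution indices (defaults 5 and 10).
#' @param seed Optional integer seed for the whole run.
#' @param hv_samples Monte-Carlo sample count for the hypervolume series when
#'   `n_obj > 2` (default 2e4).
#' @param track_hypervolume Compute the per-generation hypervolume series.
#' @return An `fs_nsga2` object: list with `genotypes` (final population
#'   matrix), `objectives` (canonical matrix), `rank`, `crowding`, `front`
#'   (row indices of the final rank-1 set), `archive` (`$genotypes`,
#'   `$objectives` of the cumulative nondominated set), `hypervolume` (tibble
#'   `generation`, `hypervolume`), `n_evaluations`, and `config`.
#' @export
#' @examples
#' # toy biobjective problem: minimize (x^2, (x - 2)^2); Pareto set x in [0, 2]
#' fn <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
#' res <- nsga2(fn, lower = 0, upper = 4, n_obj = 2,
#'              pop_size = 20, generations = 20, seed = 1)
#' range(res$genotypes[res$front, 1])
nsga2 <- function(fn, lower, upper, n_obj, pop_size = 40, generations = 30,
                  cx_prob = 0.7, mut_prob = 0.2, eta_cx = 5, eta_mut = 10,
                  seed = NULL, hv_samples = 2e4, track_hypervolume = TRUE) {
  if (pop_size < 2 || pop_size %% 2 != 0) abort("`pop_size` must be even and >= 2.")
  if (cx_prob < 0 || cx_prob > 1 || mut_prob < 0 || mut_prob > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  n_var <- length(lower)
  stopifnot(length(upper) == n_var, all(upper >= lower))
  with_seed(seed, {
    X <- matrix(stats::runif(pop_size * n_var), pop_size, n_var)
    X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
    Fm <- rbind(fn(X))
    ev_blocks <- list(Fm)  # evaluated objective rows, per generation

    arch_X <- X; arch_F <- Fm
    prune <- function(ax, af) {
      dup <- duplicated(cbind(af, ax))
      ax <- ax[!dup, , drop = FALSE]; af <- af[!dup, , drop = FALSE]
      keep <- nondominated_sort(af) == 1
      list(X = ax[keep, , drop = FALSE], F = af[keep, , drop = FALSE])
    }
    a <- prune(arch_X, arch_F); arch_X <- a$X; arch_F <- a$F

    for (gen in seq_len(generations)) {
      rc <- rank_and_crowd(Fm)
      Xo <- matrix(NA_real_, pop_size, n_var)
      for (p in seq_len(pop_size / 2)) {
        i1 <- tournament_pick(rc$rank, rc$crowding)
        i2 <- tournament_pick(rc$rank, rc$crowding)
        if (stats::runif(1) <= cx_prob) {
          ch <- sbx_pair(X[i1, ], X[i2, ], lower, upper, eta = eta_cx)
        } else {
          ch <- rbind(X[i1, ], X[i2, ])
        }
        Xo[2 * p - 1, ] <- poly_mutate(ch[1, ], lower, upper, eta_mut, mut_prob)
        Xo[2 * p, ] <- poly_mutate(ch[2, ], lower, upper, eta_mut, mut_prob)
      }
      Fo <- rbind(fn(Xo))
      ev_blocks[[gen + 1L]] <- Fo

      Xc <- rbind(X, Xo); Fc <- rbind(Fm, Fo)
      rank_c <- nondominated_sort(Fc)
      sel <- integer(0)
      for (r in sort(unique(rank_c))) {
        idx <- which(rank_c == r)
        if (length(sel) + length(idx) <= pop_size) {
          sel <- c(sel, idx)
        } else {
          cd <- crowding_distance(Fc[idx, , drop = FALSE])
          sel <- c(sel, idx[order(cd, decreasing = TRUE)][seq_len(pop_size - length(sel))])
          break
        }
      }
      X <- Xc[sel, , drop = FALSE]; Fm <- Fc[sel, , drop = FALSE]

      a <- prune(rbind(arch_X, Xo), rbind(arch_F, Fo))
      arch_X <- a$X; arch_F <- a$F
    }

    rc <- rank_and_crowd(Fm)

    hv <- NULL
    if (track_hypervolume) {
      all_F <- do.call(rbind, ev_blocks)
      ref <- apply(all_F, 2, max)
      box_lo <- apply(all_F, 2, min)
      widths <- ref - box_lo
      hv_vals <- numeric(length(ev_blocks))
      if (n_obj == 2) {
        acc <- NULL
        for (g in seq_along(ev_blocks)) {
          acc <- rbind(acc, ev_blocks[[g]])
          hv_vals[g] <- hypervolume(acc, ref, method = "exact2d")
        }
      } else if (all(widths > 0)) {
        s <- with_seed(derive_seed(seed %||% 0, 777), {
          sm <- matrix(stats::runif(hv_samples * n_obj), hv_samples, n_obj)
          sweep(sweep(sm, 2, widths, `*`), 2, box_lo, `+`)
        })
        dom <- rep(FALSE, hv_samples)
        for (g in seq_along(ev_blocks)) {
          blk <- ev_blocks[[g]]
          for (i in seq_len(nrow(blk))) {
            nd <- which(!dom)
            if (length(nd) == 0) break
            ok <- rep(TRUE, length(nd))
            for (j in seq_len(n_obj)) ok <- ok & (s[nd, j] >= blk[i, j])
            dom[nd[ok]] <- TRUE
          }
          hv_vals[g] <- mean(dom) * prod(widths)
        }
      }
      hv <- tibble(generation = seq_along(ev_blocks) - 1L, hypervolume = hv_vals)
    }

    structure(
      list(
        genotypes = X, objectives = Fm, rank = rc$rank, crowding = rc$crowding,
        front = which(rc$rank == 1L),
        archive = list(genotypes = arch_X, objectives = arch_F),
        hypervolume = hv,
        n_evaluations = pop_size * (generations + 1L),
        config = list(pop_size = pop_size, generations = generations,
                      cx_prob = cx_prob, mut_prob = mut_prob,
                      eta_cx = eta_cx, eta_mut = eta_mut, n_obj = n_obj,
                      lower = lower, upper = upper, seed = seed)
      ),
      class = "fs_nsga2"
    )
  })
}

#' @export
print.fs_nsga2 <- function(x, ...) {
  cat(sprintf(
    "<fs_nsga2> pop %d, %d generations, %d objectives; final front: %d solutions\n",
    x$config$pop_size, x$config$generations, x$config$n_obj, length(x$front)))
  if (!is.null(x$hypervolume)) {
    cat(sprintf("  archive hypervolume: %.4g -> %.4g\n",
                x$hypervolume$hypervolume[1],
                utils::tail(x$hypervolume$hypervolume, 1)))
  }
  invisible(x)
}

#' Optimize management regimes for a strategy
#'
#' Runs the full simulation-optimization for a strategy of `k` landowner
#' groups: NSGA-II over genotypes of `k` clearing intervals plus `k` group
#' weights, each genotype scored by worst-case objectives over `replicates`
#' pool landscapes ([evaluate_genotype()]). Strategies k = 1..5 are run
#' separately, as in the study design; [combine_frontiers()] pools them
#' afterwards.
#'
#' @inheritParams evaluate_genotype
#' @param pool A [generate_pool()] result.
#' @param k Number of landowner groups (1-5).
#' @param pop_size,generations,cx_prob,mut_prob,eta_cx,eta_mut,hv_samples
#'   Passed to [nsga2()].
#' @param seed Integer seed; evaluation replicate draws use per-evaluation
#'   sub-seeds derived from it, so runs are reproducible end to end.
#' @return An `fs_regime_opt` (also `fs_nsga2`) object; additionally carries
#'   `k`, `frontier` (a tidy tibble of the final rank-1 regimes with
#'   display-form objectives) and the evaluation settings.
#' @export
optimize_regimes <- function(pool, k = 3, pop_size = 40, generations = 30,
                             replicates = 4, model = uncertainty_model(),
                             horizon = 100, burn_in = 20,
                             curve = biomass_curve(), seed = 1,
                             cx_prob = 0.7, mut_prob = 0.2,
                             eta_cx = 5, eta_mut = 10, hv_samples = 2e4) {
  stopifnot(inherits(pool, "landscape_pool"), k >= 1, k <= 5)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  fn <- function(X) {
    out <- matrix(NA_real_, nrow(X), 6)
    for (i in seq_len(nrow(X))) {
      counter$n <- counter$n + 1L
      obj <- evaluate_genotype(X[i, ], k, pool, replicates = replicates,
                               model = model, horizon = horizon,
                               burn_in = burn_in, curve = curve,
                               seed = derive_seed(seed, 100000 + counter$n))
      out[i, ] <- objectives_canonical(obj)
    }
    out
  }
  res <- nsga2(fn, lower = c(rep(3, k), rep(0, k)),
               upper = c(rep(NO_MANAGEMENT, k), rep(1, k)),
               n_obj = 6, pop_size = pop_size, generations = generations,
               cx_prob = cx_prob, mut_prob = mut_prob,
               eta_cx = eta_cx, eta_mut = eta_mut,
               seed = derive_seed(seed, 1), hv_samples = hv_samples)
  res$k <- k
  res$eval_config <- list(replicates = replicates, horizon = horizon,
                          burn_in = burn_in, model = model, seed = seed)
  res$frontier <- frontier_tibble(res)
  class(res) <- c("fs_regime_opt", class(res))
  res
}

# Tidy frontier (rank-1) tibble for a regime optimization result.
frontier_tibble <- function(res, all_ranks = FALSE) {
  idx <- if (all_ranks) seq_len(nrow(res$genotypes)) else res$front
  k <- res$k
  regimes <- lapply(idx, function(i) decode_genotype(res$genotypes[i, ], k))
  obj <- objectives_display(res$objectives[idx, , drop = FALSE])
  out <- tibble(
    solution = seq_along(idx),
    k = k,
    n_groups_effective = vapply(regimes, function(r) sum(r$proportions > 1e-9), 0L),
    regime = regimes,
    rank = res$rank[idx],
    crowding = res$crowding[idx]
  )
  dplyr::bind_cols(out, obj)
}

#' Pool frontiers from several strategies
#'
#' Combines the rank-1 frontiers of separate per-strategy runs into one table
#' and recomputes Pareto ranks across strategies, for joint level-diagram
#' scoring and strategy comparison.
#'
#' @param ... `fs_regime_opt` objects (or a single list of them).
#' @return A tibble like the per-run `frontier`, with `rank` recomputed over
#'   the pooled set (1 = nondominated across all strategies).
#' @export
combine_frontiers <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "fs_regime_opt")) runs <- runs[[1]]
  fronts <- purrr::map_dfr(runs, function(r) r$frontier)
  fronts$solution <- seq_len(nrow(fronts))
  can <- objectives_canonical(fronts[, obj_names()])
  fronts$rank <- nondominated_sort(can)
  fronts
}

#' Write a frontier to CSV
#'
#' Flattens the regime list-column into `interval_1..5` / `proportion_1..5`
#' columns alongside the display-form objectives, rank and crowding.
#'
#' @param frontier A frontier tibble (from `$frontier` or [combine_frontiers()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frontier <- function(frontier, path) {
  flat <- purrr::map_dfr(frontier$regime, function(r) {
    iv <- pr <- rep(NA_real_, 5)
    iv[seq_len(r$n_groups)] <- r$intervals
    pr[seq_len(r$n_groups)] <- r$proportions
    stats::setNames(as.list(c(iv, pr)),
                    c(paste0("interval_", 1:5), paste0("proportion_", 1:5)))
  })
  out <- dplyr::bind_cols(
    frontier[, setdiff(names(frontier), "regime")], flat)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
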
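# Independent brute-force oracles used across the suite. Deliberately naive:
# plain double loops, no shared code with the package implementations.

# Iterative-removal nondominated ranking.
oracle_sort <- function(m) {
  n <- nrow(m)
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    r <- r + 1L
    left <- which(is.na(rank))
    for (i in left) {
      dominated <- FALSE
      for (j in left) {
        if (j != i && all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) rank[i] <- r
    }
  }
  rank
}

# Direct crowding distance for one front.
oracle_crowding <- function(m) {
  n <- nrow(m)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(m))) {
    ord <- order(m[, k])
    rng <- m[ord[n], k] - m[ord[1], k]
    if (rng > 0) {
      d[ord[1]] <- Inf
      d[ord[n]] <- Inf
      for (p in 2:(n - 1)) {
        d[ord[p]] <- d[ord[p]] + (m[ord[p + 1], k] - m[ord[p - 1], k]) / rng
      }
    }
  }
  d
}

# Variance of absolute adjacent differences via explicit loop.
oracle_edge_contrast <- function(b, pairs) {
  ds <- numeric(0)
  for (p in seq_len(nrow(pairs))) {
    ds <- c(ds, abs(b[pairs[p, 1]] - b[pairs[p, 2]]))
  }
  mean((ds - mean(ds))^2)
}

# Exact hypervolume of <= 3 points via inclusion-exclusion on boxes
# [point, ref].
oracle_hv_boxes <- function(pts, ref) {
  vol <- function(lo) prod(pmax(ref - lo, 0))
  n <- nrow(pts)
  total <- 0
  for (size in seq_len(n)) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      corner <- apply(pts[comb, , drop = FALSE], 2, max)  # box intersection
      total <- total + (-1)^(size + 1) * vol(corner)
    }
  }
  total
}

# Classical scaling by explicit double centering + eigendecomposition.
oracle_pcoa <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2)
  keep <- e$values > 1e-10
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                     nrow = sum(keep))
  list(coordinates = coords, eigenvalues = e$values)
}

# BFS over a neighbour list; returns the set of reachable cells.
oracle_bfs <- function(neighbors, start, allowed) {
  seen <- logical(length(neighbors))
  seen[start] <- TRUE
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in neighbors[[v]]) {
      if (allowed[w] && !seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  which(seen)
}

# Minimal hand-built landscape: every owner's cells contiguous by rows.
manual_landscape <- function(n_rows, n_cols, owner, age) {
  g <- hex_grid(n_rows, n_cols)
  l <- g$cells
  l$owner <- as.integer(owner)
  l$age <- as.integer(age)
  structure(l, class = c("hex_landscape", class(g$cells)),
            grid = g, landscape_id = 0L)
}

# A small display-form objective tibble for post-processing tests.
random_frontier <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cost = runif(n, 0, 30),
    fuel_load = runif(n, 5000, 20000),
    edge_contrast = runif(n, 0, 5e7),
    skewness = runif(n, -2, 2),
    mid_area = runif(n, 0, 40),
    late_area = runif(n, 0, 40)
  )
}
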
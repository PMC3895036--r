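#' Build a hexagonal-cell grid
#'
#' Constructs an offset-row ("odd-r": odd rows, counting from 0, are shifted
#' half a cell to the right) lattice of 1-ha hexagonal cells. Interior cells
#' have six neighbours; boundary cells have two to five. The hexagon geometry
#' itself never enters any computed quantity — only the adjacency structure and
#' the 1-ha cell area do — so cell area equals cell count in hectares.
#'
#' @param n_rows,n_cols Positive lattice dimensions.
#' @return A `hex_grid` object: a list with `n_rows`, `n_cols`, `n_cells`,
#'   `cell_area` (1 ha), `cells` (a tibble with `cell`, `row`, `col`),
#'   `neighbors` (list of integer neighbour vectors, indexed by cell), and
#'   `pairs` (two-column integer matrix of unordered adjacent pairs, each
#'   counted once).
#' @export
#' @examples
#' g <- hex_grid(3, 3)
#' g$neighbors[[5]] # the interior cell of a 3x3 grid has 6 neighbours
hex_grid <- function(n_rows, n_cols) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      length(n_rows) != 1 || length(n_cols) != 1 ||
      n_rows < 1 || n_cols < 1 || n_rows != floor(n_rows) || n_cols != floor(n_cols)) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  # 0-based row/col for offset arithmetic
  r <- rep(0:(n_rows - 1L), each = n_cols)
  c <- rep(0:(n_cols - 1L), times = n_rows)

  # odd-r offsets: odd rows shifted right
  off_even <- cbind(dr = c(0L, 0L, -1L, -1L, 1L, 1L), dc = c(-1L, 1L, -1L, 0L, -1L, 0L))
  off_odd  <- cbind(dr = c(0L, 0L, -1L, -1L, 1L, 1L), dc = c(-1L, 1L, 0L, 1L, 0L, 1L))

  from <- integer(0); to <- integer(0)
  for (k in 1:6) {
    dr <- ifelse(r %% 2L == 0L, off_even[k, 1], off_odd[k, 1])
    dc <- ifelse(r %% 2L == 0L, off_even[k, 2], off_odd[k, 2])
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 0L & rr < n_rows & cc >= 0L & cc < n_cols
    from <- c(from, which(ok))
    to <- c(to, (rr * n_cols + cc + 1L)[ok])
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  neighbors <- unname(split(to, factor(from, levels = seq_len(n))))
  keep <- from < to
  pairs <- cbind(i = from[keep], j = to[keep])

  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, n_cells = n, cell_area = 1,
      cells = tibble(cell = seq_len(n), row = r + 1L, col = c + 1L),
      neighbors = neighbors, pairs = pairs
    ),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d x %d (%d cells of %g ha, %d adjacent pairs)\n",
              x$n_rows, x$n_cols, x$n_cells, x$cell_area, nrow(x$pairs)))
  invisible(x)
}

#' Moment-matched Gamma parameters
#'
#' Converts a (mean, variance) pair into the (shape, scale) parameterization of
#' the Gamma distribution: shape = mean^2/variance, scale = variance/mean.
#'
#' @param mean,variance Positive moments (ha and ha^2 for landholding areas).
#' @return Named numeric vector with `shape` and `scale`.
#' @export
#' @examples
#' gamma_params(20, 100) # shape 4, scale 5
gamma_params <- function(mean, variance) {
  if (!is.numeric(mean) || !is.numeric(variance) || mean <= 0 || variance <= 0) {
    abort("`mean` and `variance` must be positive.")
  }
  c(shape = mean^2 / variance, scale = variance / mean)
}

#' Landholding-area distribution
#'
#' The distribution of landholding (private property) areas used when
#' partitioning a landscape. Areas are Gamma distributed; the defaults
#' (mean 20 ha, variance 100 ha^2) describe a fine-grained multi-ownership
#' landscape where most holdings are under 10-40 ha.
#'
#' @param mean Mean holding area in ha (default 20).
#' @param variance Variance of holding area in ha^2 (default 100).
#' @return An `area_distribution` list with `mean`, `variance`, `shape`, `scale`.
#' @export
#' @examples
#' area_distribution()          # the base landscape
#' area_distribution(100, 2500) # a coarser-grained sweep level
area_distribution <- function(mean = 20, variance = 100) {
  p <- gamma_params(mean, variance)
  structure(list(mean = mean, variance = variance,
                 shape = unname(p["shape"]), scale = unname(p["scale"])),
            class = "area_distribution")
}

#' @export
print.area_distribution <- function(x, ...) {
  cat(sprintf("<area_distribution> Gamma(mean = %g ha, var = %g ha^2; shape = %g, scale = %g)\n",
              x$mean, x$variance, x$shape, x$scale))
  invisible(x)
}

#' Sample landholding target areas
#'
#' Draws target areas (in cells, i.e. ha) from an [area_distribution()],
#' rounded to the nearest integer and floored at one cell.
#'
#' @param n Number of draws.
#' @param dist An [area_distribution()].
#' @param seed Optional integer seed.
#' @param raw If `TRUE`, return the continuous Gamma draws without rounding.
#' @return Numeric vector of length `n`.
#' @export
sample_target_areas <- function(n, dist = area_distribution(), seed = NULL, raw = FALSE) {
  stopifnot(inherits(dist, "area_distribution"))
  with_seed(seed, {
    x <- stats::rgamma(n, shape = dist$shape, scale = dist$scale)
    if (raw) x else pmax(1, round(x))
  })
}

#' Partition a hex grid into contiguous landholdings
#'
#' Region-growing partition: repeatedly pick a uniformly random seed cell among
#' unassigned cells, draw a target area from the Gamma distribution (rounded,
#' floored at 1 cell), and expand the patch by uniformly random draws from its
#' unassigned frontier until the target is reached or the frontier is
#' exhausted; repeat until every cell has an owner. Realized areas only
#' approximately follow the Gamma because late patches are squeezed by earlier
#' ones.
#'
#' @param grid A [hex_grid()].
#' @param dist An [area_distribution()].
#' @param seed Optional integer seed.
#' @return Integer vector of owner ids (1-based, one per cell).
#' @export
partition_landholdings <- function(grid, dist = area_distribution(), seed = NULL) {
  stopifnot(inherits(grid, "hex_grid"))
  with_seed(seed, {
    n <- grid$n_cells
    nb <- grid$neighbors
    owner <- integer(n)
    unassigned <- seq_len(n)
    next_owner <- 0L
    while (length(unassigned) > 0) {
      next_owner <- next_owner + 1L
      target <- max(1, round(stats::rgamma(1, shape = dist$shape, scale = dist$scale)))
      seed_cell <- unassigned[sample.int(length(unassigned), 1L)]
      owner[seed_cell] <- next_owner
      size <- 1L
      frontier <- nb[[seed_cell]][owner[nb[[seed_cell]]] == 0L]
      while (size < target && length(frontier) > 0) {
        pick <- frontier[sample.int(length(frontier), 1L)]
        owner[pick] <- next_owner
        size <- size + 1L
        cand <- nb[[pick]]
        cand <- cand[owner[cand] == 0L]
        frontier <- unique(c(frontier[frontier != pick], cand))
      }
      unassigned <- unassigned[owner[unassigned] == 0L]
    }
    owner
  })
}

#' Assign initial understory ages to landholdings
#'
#' Each landholding gets one age since the last understory clearing, drawn
#' uniformly on the integers 0-70 years (the simulator advances age in 1-year
#' steps); all cells of a holding share it. This emulates the heterogeneous
#' mosaic of management histories found in the study system.
#'
#' @param landscape A `hex_landscape` (see [hex_landscape()]).
#' @param seed Optional integer seed.
#' @return The landscape with its `age` column filled.
#' @export
assign_initial_ages <- function(landscape, seed = NULL) {
  stopifnot(inherits(landscape, "hex_landscape"))
  with_seed(seed, {
    owners <- sort(unique(landscape$owner))
    ages <- sample(0:70, length(owners), replace = TRUE)
    landscape$age <- ages[match(landscape$owner, owners)]
    landscape
  })
}

#' Generate one random multi-ownership landscape
#'
#' Builds a hex grid, partitions it into contiguous Gamma-area landholdings and
#' assigns per-holding initial understory ages.
#'
#' @param n_rows,n_cols Lattice dimensions (1-ha cells).
#' @param dist An [area_distribution()].
#' @param seed Optional integer seed (drives both the partition and the ages).
#' @param id Landscape identifier stored on the object.
#' @return A `hex_landscape`: a tibble with columns `cell`, `row`, `col`,
#'   `owner`, `age`, carrying the `hex_grid` and `landscape_id` as attributes.
#' @export
#' @examples
#' l <- hex_landscape(10, 10, seed = 1)
#' dplyr::count(l, owner)
hex_landscape <- function(n_rows, n_cols, dist = area_distribution(),
                          seed = NULL, id = 1L) {
  grid <- hex_grid(n_rows, n_cols)
  with_seed(seed, {
    owner <- partition_landholdings(grid, dist)
    out <- grid$cells
    out$owner <- owner
    out$age <- NA_integer_
    out <- structure(out, class = c("hex_landscape", class(out)),
                     grid = grid, landscape_id = id)
    assign_initial_ages(out)
  })
}

#' Extract the grid of a landscape
#' @param landscape A `hex_landscape`.
#' @return The underlying [hex_grid()].
#' @export
landscape_grid <- function(landscape) {
  stopifnot(inherits(landscape, "hex_landscape"))
  attr(landscape, "grid")
}

#' Generate a pool of random landscapes
#'
#' A pool of independent random landscapes is pre-generated once and reused
#' across solution evaluations, avoiding the overhead of building a fresh
#' landscape for every evaluation. The full-scale configuration uses a pool of
#' 2000 landscapes of 180 x 180 cells; tests use far smaller presets.
#'
#' @param n Pool size.
#' @param n_rows,n_cols Lattice dimensions.
#' @param dist An [area_distribution()].
#' @param seed Base seed; landscape `i` uses `derive_seed(seed, i)`, so pools
#'   are reproducible and members mutually independent.
#' @return A `landscape_pool`: list of `hex_landscape` objects with attributes
#'   `pool_seed`, `n_rows`, `n_cols`, `dist`.
#' @export
#' @examples
#' pool <- generate_pool(3, 8, 8, seed = 7)
#' length(pool)
generate_pool <- function(n, n_rows, n_cols, dist = area_distribution(), seed = 1L) {
  stopifnot(n >= 1)
  landscapes <- lapply(seq_len(n), function(i) {
    hex_landscape(n_rows, n_cols, dist, seed = derive_seed(seed, i), id = i)
  })
  structure(landscapes, class = "landscape_pool",
            pool_seed = seed, n_rows = n_rows, n_cols = n_cols, dist = dist)
}

#' @export
print.landscape_pool <- function(x, ...) {
  d <- attr(x, "dist")
  cat(sprintf("<landscape_pool> %d landscapes of %d x %d cells (areas ~ Gamma mean %g, var %g; seed %s)\n",
              length(x), attr(x, "n_rows"), attr(x, "n_cols"),
              d$mean, d$variance, format(attr(x, "pool_seed"))))
  invisible(x)
}

#' Write / read a landscape as CSV
#'
#' One row per cell with columns `cell_id,row,col,owner_id,age`.
#'
#' @param landscape A `hex_landscape`.
#' @param path Output CSV path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns a `hex_landscape`.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "hex_landscape"))
  out <- tibble(cell_id = landscape$cell, row = landscape$row, col = landscape$col,
                owner_id = landscape$owner, age = landscape$age)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param id Landscape identifier for the reconstructed object.
#' @export
read_landscape <- function(path, id = 1L) {
  d <- utils::read.csv(path)
  grid <- hex_grid(max(d$row), max(d$col))
  out <- grid$cells
  ord <- match(out$cell, d$cell_id)
  out$owner <- as.integer(d$owner_id[ord])
  out$age <- as.integer(d$age[ord])
  structure(out, class = c("hex_landscape", class(grid$cells)),
            grid = grid, landscape_id = id)
}

#' Write a landscape pool to a directory
#'
#' Writes one CSV per landscape plus a JSON manifest (`pool.json`) recording
#' the seed, grid dimensions and area-distribution parameters.
#'
#' @param pool A [generate_pool()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "landscape_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pool)) {
    write_landscape(pool[[i]], file.path(dir, sprintf("landscape_%04d.csv", i)))
  }
  d <- attr(pool, "dist")
  manifest <- list(pool_seed = attr(pool, "pool_seed"), n = length(pool),
                   n_rows = attr(pool, "n_rows"), n_cols = attr(pool, "n_cols"),
                   area_mean = d$mean, area_variance = d$variance)
  jsonlite::write_json(manifest, file.path(dir, "pool.json"), auto_unbox = TRUE)
  invisible(dir)
}
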
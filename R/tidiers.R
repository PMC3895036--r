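#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an NSGA-II result
#'
#' One row per final-population solution with its Pareto rank, crowding
#' distance and objective values. For regime optimizations ([optimize_regimes()])
#' the objectives are reported in display form and the decoded regime is
#' attached as a list-column; by default only the rank-1 frontier is returned.
#'
#' @param x An `fs_nsga2` / `fs_regime_opt` object.
#' @param all_ranks Include dominated solutions too (default `FALSE` for
#'   regime runs, `TRUE` for the generic engine).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fs_nsga2 <- function(x, all_ranks = TRUE, ...) {
  idx <- if (all_ranks) seq_len(nrow(x$genotypes)) else x$front
  obj <- x$objectives[idx, , drop = FALSE]
  colnames(obj) <- paste0("objective_", seq_len(ncol(obj)))
  dplyr::bind_cols(
    tibble(solution = seq_along(idx), rank = x$rank[idx], crowding = x$crowding[idx]),
    as_tibble(obj)
  )
}

#' @rdname tidy.fs_nsga2
#' @export
tidy.fs_regime_opt <- function(x, all_ranks = FALSE, ...) {
  frontier_tibble(x, all_ranks = all_ranks)
}

#' Summarize an NSGA-II run in one row
#'
#' @param x An `fs_nsga2` object.
#' @param ... Unused.
#' @return A one-row tibble: population size, generations, evaluation count,
#'   frontier size, and the final archive hypervolume (when tracked).
#' @export
glance.fs_nsga2 <- function(x, ...) {
  tibble(
    pop_size = x$config$pop_size,
    generations = x$config$generations,
    n_evaluations = x$n_evaluations,
    n_front = length(x$front),
    hypervolume = if (is.null(x$hypervolume)) NA_real_ else
      utils::tail(x$hypervolume$hypervolume, 1)
  )
}
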
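#' Swap local search on the iteration-best solution
#'
#' Repeatedly exchanges one protected and one unprotected cell: the protected
#' cell whose release most improves the objective is removed, then the
#' configurable unprotected cell whose protection most improves the objective
#' (given that removal) is added. Both picks use exact incremental deltas;
#' the exchange is kept only if the combined change is strictly positive,
#' otherwise the move is undone and the search stops. At most `n_swaps`
#' exchanges are attempted, drawn uniformly from `swap_range` when not given,
#' so fitness is non-decreasing and the search stops early at a swap-local
#' optimum.
#'
#' Choosing the pair as best-removal-then-best-addition evaluates
#' `Q + (N - Q)` candidates per exchange instead of all `Q * (N - Q)` pairs;
#' the accepted delta is still the exact joint effect of the pair.
#'
#' @inheritParams objectives
#' @param solution Feasible solution matrix to improve.
#' @param n_swaps Maximum number of exchanges; default: uniform draw from
#'   `swap_range`.
#' @param swap_range Integer `(low, high)` bounds for the default draw.
#' @return A list with `solution`, `fitness` and `swaps` (number of
#'   exchanges actually kept).
#' @examples
#' g <- suitability_grid(matrix(runif(100), 10, 10))
#' set.seed(2)
#' x <- init_complete_random(g, 12)
#' out <- swap_local_search(x, g, zoning_weights(0.4, 0.3, 0.3), Q = 12)
#' out$fitness >= evaluate_fitness(x, g, c(0.4, 0.3, 0.3))
#' @export
swap_local_search <- function(solution, grid, weights, Q = sum(solution),
                              n_swaps = NULL, swap_range = c(20L, 40L),
                              window = 3) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, Q)
  w <- check_weights(weights)
  window <- check_window(window)
  if (is.null(n_swaps)) n_swaps <- draw_swap_count(swap_range)
  st <- state_new(grid, solution, w, Q, window)
  k <- swap_state(st, n_swaps)
  list(solution = state_solution(st, grid), fitness = zb_fitness(st),
       swaps = k)
}

draw_swap_count <- function(swap_range) {
  lo <- as.integer(swap_range[[1]]); hi <- as.integer(swap_range[[2]])
  if (lo > hi) stop("swap_range low > high", call. = FALSE)
  if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
}

# In-place greedy swap search on a state; returns the number of kept swaps.
# Acceptance threshold slightly above zero guards against accepting pure
# floating-point noise and cycling.
swap_state <- function(st, n_swaps, eps = 1e-12) {
  kept <- 0L
  for (t in seq_len(n_swaps)) {
    br <- zb_best_rem(st)
    if (br$index == 0L) break
    zb_toggle(st, br$index)
    ba <- zb_best_add(st)
    if (ba$index == 0L || br$gain + ba$gain <= eps) {
      zb_toggle(st, br$index)  # undo; no improving exchange exists
      break
    }
    zb_toggle(st, ba$index)
    kept <- kept + 1L
  }
  kept
}
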
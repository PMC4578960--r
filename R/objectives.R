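#' Zoning sub-objectives and their weighted combination
#'
#' A protection scheme is scored by three normalized criteria, each averaged
#' over the `Q` protected cells:
#'
#' * **Ecological suitability**: `sum(eco[x]) / Q` (maximized).
#' * **Development potential**: `sum(dev[x]) / Q` (minimized; it enters the
#'   combined objective as `1 - Development`).
#' * **Compactness** (neighborhood density): for each protected cell, the
#'   proportion of protected cells among the configurable cells in the
#'   `window x window` neighborhood centered on it (window truncated at the
#'   raster border, center cell included); averaged over protected cells.
#'
#' The combined fitness is
#' `w1 * Ecological + w2 * (1 - Development) + w3 * Compactness`, which lies
#' in `[0, 1]` for normalized layers and valid weights. Larger is better.
#'
#' @param solution Logical matrix with exactly `Q` `TRUE` cells, all on
#'   configurable positions.
#' @param grid A [suitability_grid()].
#' @param Q Protection quota (number of protected cells). Defaults to the
#'   number of `TRUE` cells in `solution`.
#' @param window Odd neighborhood side length for compactness (default 3).
#' @param weights Length-3 weights, see [zoning_weights()].
#'
#' @return A scalar in `[0, 1]`.
#' @examples
#' g <- suitability_grid(matrix(runif(36), 6, 6))
#' x <- matrix(FALSE, 6, 6); x[2:3, 2:4] <- TRUE
#' evaluate_fitness(x, g, zoning_weights(0.34, 0.33, 0.33))
#' @name objectives
NULL

#' @rdname objectives
#' @export
evaluate_ecological <- function(solution, grid, Q = sum(solution)) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, Q)
  sum(grid$eco[solution]) / Q
}

#' @rdname objectives
#' @export
evaluate_development <- function(solution, grid, Q = sum(solution)) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, Q)
  sum(grid$dev[solution]) / Q
}

#' Neighborhood-density compactness of a single cell
#'
#' Proportion of protected cells among the configurable cells in the
#' `window x window` neighborhood centered on `cell` (truncated at the
#' border, center included). Returns 0 when the window holds no configurable
#' cell, so the operation is total even on fully blocked neighborhoods.
#'
#' @inheritParams objectives
#' @param cell Integer `(row, col)` pair, 1-based.
#' @return A scalar in `[0, 1]`.
#' @export
cell_compactness <- function(solution, grid, cell, window = 3) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, feasible = FALSE)
  window <- check_window(window)
  r <- cell[[1]]; c <- cell[[2]]
  if (r < 1 || r > grid$n_rows || c < 1 || c > grid$n_cols)
    stop("cell (", r, ", ", c, ") is outside the grid", call. = FALSE)
  h <- (window - 1L) %/% 2L
  rows <- max(1L, r - h):min(grid$n_rows, r + h)
  cols <- max(1L, c - h):min(grid$n_cols, c + h)
  d <- sum(grid$configurable[rows, cols])
  if (d == 0) return(0)
  sum(solution[rows, cols]) / d
}

#' @rdname objectives
#' @export
evaluate_compactness <- function(solution, grid, Q = sum(solution),
                                 window = 3) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, Q)
  window <- check_window(window)
  com <- compactness_layer(solution, grid, window)
  sum(com[solution]) / Q
}

# per-cell neighborhood density for every cell (0 where no configurable
# neighbors); vectorized via summed-area windows
compactness_layer <- function(solution, grid, window) {
  P <- window_sum(solution + 0, window)
  D <- window_sum(grid$configurable + 0, window)
  com <- ifelse(D > 0, P / D, 0)
  dim(com) <- dim(solution)
  com
}

#' @rdname objectives
#' @export
evaluate_fitness <- function(solution, grid, weights, Q = sum(solution),
                             window = 3) {
  w <- check_weights(weights)
  eco <- evaluate_ecological(solution, grid, Q)
  dev <- evaluate_development(solution, grid, Q)
  com <- evaluate_compactness(solution, grid, Q, window)
  unname(w[1] * eco + w[2] * (1 - dev) + w[3] * com)
}

#' Exact fitness change of moving one protected cell
#'
#' Computes `evaluate_fitness(after) - evaluate_fitness(before)` for the move
#' that unprotects `toggle_off` and protects `toggle_on`, without evaluating
#' either full solution: the incremental bookkeeping is O(window^2) per
#' toggle. This is the primitive behind the best-alteration repair and the
#' swap local search.
#'
#' @inheritParams objectives
#' @param toggle_off `(row, col)` of a currently protected cell.
#' @param toggle_on `(row, col)` of a configurable, unprotected cell.
#' @return The scalar fitness difference.
#' @export
fitness_delta <- function(solution, grid, weights, toggle_off, toggle_on,
                          Q = sum(solution), window = 3) {
  grid <- check_grid(grid)
  solution <- check_solution(solution, grid, Q)
  w <- check_weights(weights)
  window <- check_window(window)
  i_off <- cell_index(toggle_off, grid)
  i_on <- cell_index(toggle_on, grid)
  if (!solution[i_off])
    stop("toggle_off cell is not protected", call. = FALSE)
  if (solution[i_on])
    stop("toggle_on cell is already protected", call. = FALSE)
  if (!grid$configurable[i_on])
    stop("toggle_on cell is not configurable", call. = FALSE)
  st <- state_new(grid, solution, w, Q, window)
  d1 <- zb_gain_rem(st, i_off)
  zb_toggle(st, i_off)
  d1 + zb_gain_add(st, i_on)
}

cell_index <- function(cell, grid) {
  r <- as.integer(cell[[1]]); c <- as.integer(cell[[2]])
  if (r < 1 || r > grid$n_rows || c < 1 || c > grid$n_cols)
    stop("cell (", r, ", ", c, ") is outside the grid", call. = FALSE)
  (c - 1L) * grid$n_rows + r
}
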
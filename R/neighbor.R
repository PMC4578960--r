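#' Replace-and-alter neighbor generation
#'
#' A neighbor of solution `u_j` is built by copying a region from another
#' food source `u_k` ("replace") and then toggling cells outside that region
#' to restore the protection quota ("alter"). Two region strategies and two
#' alteration strategies are mixed at random:
#'
#' * **R1** ([replace_region_rect()]): a rectangle with uniform random
#'   position and side lengths up to a quarter of each grid dimension,
#'   clipped at the border.
#' * **R2** ([replace_region_poor()]): the `m` protected cells of `u_j` with
#'   the lowest site attribute score, `m` drawn uniformly from
#'   `1..ceiling(0.1 * Q)`.
#' * **A1** (`strategy = "best"` in [alter_repair()]): each balancing toggle
#'   picks the eligible cell outside the region whose toggle most improves
#'   the objective (exact incremental delta; ties to the lowest row-major
#'   position).
#' * **A2** (`strategy = "random"`): each balancing toggle picks uniformly
#'   among eligible outside cells.
#'
#' Only the direction that restores the quota is toggled: excess protected
#' cells are released, deficits are filled from configurable unprotected
#' cells. If no eligible cell remains the move is degenerate and
#' [generate_neighbor()] returns `u_j` unchanged.
#'
#' @param xj,xk Feasible solution matrices over the same grid.
#' @inheritParams objectives
#' @return `replace_region_rect()` / `replace_region_poor()`: a list with
#'   `solution` (the overwritten matrix, possibly off-quota) and `region`
#'   (linear cell indices). `alter_repair()`: a feasible solution matrix, or
#'   `NULL` if repair is infeasible. `generate_neighbor()`: a feasible
#'   solution matrix; attribute `"degenerate"` is `TRUE` when the move was
#'   reverted.
#' @examples
#' g <- suitability_grid(matrix(runif(64), 8, 8))
#' set.seed(1)
#' a <- init_complete_random(g, 10); b <- init_complete_random(g, 10)
#' v <- generate_neighbor(a, b, g, zoning_weights(0.4, 0.3, 0.3), Q = 10)
#' sum(v)
#' @name neighbor
NULL

# uniform rectangle: top-left uniform on the grid, side lengths uniform on
# 1..ceiling(dim/4), clipped at the borders; returns linear indices
rect_region <- function(nr, nc) {
  r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
  hgt <- sample.int(ceiling(nr / 4), 1)
  wid <- sample.int(ceiling(nc / 4), 1)
  rows <- r0:min(nr, r0 + hgt - 1L)
  cols <- c0:min(nc, c0 + wid - 1L)
  as.integer(outer(rows, (cols - 1L) * nr, `+`))
}

#' @rdname neighbor
#' @export
replace_region_rect <- function(xj, xk, grid) {
  grid <- check_grid(grid)
  xj <- check_solution(xj, grid)
  xk <- check_solution(xk, grid)
  region <- rect_region(grid$n_rows, grid$n_cols)
  xj[region] <- xk[region]
  list(solution = xj, region = region)
}

# the m protected cells of xj with the lowest site score (ties by row-major)
poor_region <- function(xj, grid, w, m, s = NULL, key = NULL) {
  if (is.null(s)) s <- site_score(grid, w)
  if (is.null(key)) key <- rm_order_key(grid$n_rows, grid$n_cols)
  prot <- which(xj)
  m <- min(m, length(prot))
  prot[order(s[prot], key[prot])[seq_len(m)]]
}

#' @rdname neighbor
#' @param weights Length-3 weights (site part defines cell quality for R2).
#' @param size Region size for R2; defaults to a uniform draw on
#'   `1..ceiling(0.1 * sum(xj))`.
#' @export
replace_region_poor <- function(xj, xk, grid, weights, size = NULL) {
  grid <- check_grid(grid)
  xj <- check_solution(xj, grid)
  xk <- check_solution(xk, grid)
  w <- check_weights(weights)
  m <- if (is.null(size))
    sample.int(max(1L, ceiling(0.1 * sum(xj))), 1) else as.integer(size)
  if (m == 0) return(list(solution = xj, region = integer(0)))
  region <- poor_region(xj, grid, w, m)
  xj[region] <- xk[region]
  list(solution = xj, region = region)
}

# Repair a state in place to count == Q, toggling only outside `region`.
# Returns TRUE on success, FALSE when no eligible cell remains.
repair_state <- function(st, region, Q, best) {
  d <- zb_count(st) - Q
  if (d == 0L) return(TRUE)
  zb_set_region(st, region)
  ok <- TRUE
  for (t in seq_len(abs(d))) {
    if (best) {
      b <- if (d > 0) zb_best_rem(st) else zb_best_add(st)
      i <- b$index
    } else {
      i <- zb_rand_eligible(st, protected_side = d > 0, stats::runif(1))
    }
    if (i == 0L) { ok <- FALSE; break }
    zb_toggle(st, i)
  }
  zb_clear_region(st)
  ok
}

#' @rdname neighbor
#' @param x A possibly off-quota solution matrix (output of a replacement).
#' @param region Linear indices of the replaced region (excluded from
#'   alteration).
#' @param strategy `"best"` (A1) or `"random"` (A2).
#' @export
alter_repair <- function(x, region, grid, weights, Q,
                         strategy = c("best", "random"), window = 3) {
  grid <- check_grid(grid)
  x <- check_solution(x, grid, feasible = FALSE)
  if (any(x & !grid$configurable))
    stop("input protects non-configurable cells", call. = FALSE)
  w <- check_weights(weights)
  window <- check_window(window)
  strategy <- match.arg(strategy)
  st <- state_new(grid, x, w, Q, window)
  if (!repair_state(st, region, Q, best = strategy == "best")) return(NULL)
  state_solution(st, grid)
}

#' @rdname neighbor
#' @param p_rect Probability of the rectangle strategy R1 (else R2).
#' @param p_best_alter Probability of the best-position alteration A1
#'   (else A2).
#' @export
generate_neighbor <- function(xj, xk, grid, weights, Q,
                              window = 3, p_rect = 0.5, p_best_alter = 0.5) {
  grid <- check_grid(grid)
  xj <- check_solution(xj, grid, Q)
  xk <- check_solution(xk, grid, Q)
  w <- check_weights(weights)
  window <- check_window(window)
  st <- state_new(grid, xj, w, Q, window)
  res <- neighbor_state(st, as.logical(xk), xj, grid, w, Q, window,
                        p_rect, p_best_alter)
  if (res$degenerate) return(structure(xj, degenerate = TRUE))
  structure(state_solution(res$st, grid), degenerate = FALSE)
}

# Core replace-and-alter move on states (used by the optimizer loop).
# `st_j` is not modified; `xk` is the neighbor's solution as a plain logical
# vector.  Returns list(st, fitness, degenerate).
neighbor_state <- function(st_j, xk, xj, grid, w, Q, window,
                           p_rect, p_best_alter, s = NULL, key = NULL) {
  if (stats::runif(1) < p_rect) {
    region <- rect_region(grid$n_rows, grid$n_cols)
  } else {
    m <- sample.int(max(1L, ceiling(0.1 * Q)), 1)
    region <- poor_region(xj, grid, w, m, s, key)
  }
  st <- zb_clone(st_j)
  changed <- zb_apply_values(st, region, xk[region])
  if (changed == 0L)
    return(list(st = st, fitness = zb_fitness(st), degenerate = FALSE))
  best <- stats::runif(1) < p_best_alter
  if (!repair_state(st, region, Q, best))
    return(list(st = st_j, fitness = zb_fitness(st_j), degenerate = TRUE))
  list(st = st, fitness = zb_fitness(st), degenerate = FALSE)
}
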
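#' Density-slicing baseline
#'
#' The classic deterministic zoning baseline: the site attribute score
#' `s_i = (w1 * eco + w2 * (1 - dev)) / (w1 + w2)` is thresholded so that
#' exactly `Q` configurable cells pass, i.e. the top-`Q` cells by score are
#' protected (the implied slicing threshold is the `Q`-th largest score).
#' Ties at the threshold are broken by lowest row-major position, so the
#' result is fully deterministic and a repeated run returns an identical
#' solution.
#'
#' Density slicing optimizes the site-only part of the objective exactly: for
#' `w3 = 0` no feasible solution has higher [evaluate_fitness()]. It ignores
#' compactness entirely, which is why its spatial patterns fragment compared
#' to the bee-colony optimizer.
#'
#' @inheritParams objectives
#' @param weights Length-3 weights; only the two site weights enter the
#'   score.
#' @return A logical solution matrix with exactly `Q` protected cells.
#' @examples
#' g <- suitability_grid(matrix(runif(100), 10, 10))
#' x <- density_slice(g, 15, zoning_weights(0.5, 0.5, 0))
#' sum(x)
#' @export
density_slice <- function(grid, Q, weights) {
  grid <- check_grid(grid)
  Q <- check_quota(Q, grid)
  w <- check_weights(weights)
  s <- site_score(grid, w)
  cand <- which(grid$configurable)
  key <- rm_order_key(grid$n_rows, grid$n_cols)[cand]
  pick <- cand[order(-s[cand], key)[seq_len(Q)]]
  sol <- array(FALSE, dim(grid$eco))
  sol[pick] <- TRUE
  sol
}
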
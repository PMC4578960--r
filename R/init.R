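#' Population initialization for the bee colony
#'
#' Two initializers build the starting food sources (candidate solutions):
#'
#' * **Complete-random**: `Q` distinct configurable cells drawn uniformly
#'   without replacement — the conventional start used by most allocation
#'   metaheuristics; maximally diverse, low quality.
#' * **Pseudo-random**: seeds the solution with the top
#'   `floor(best_fraction * Q)` configurable cells ranked by the site
#'   attribute score `s_i = (w1*eco + w2*(1 - dev)) / (w1 + w2)` (ties broken
#'   by lowest row-major position), then fills the remainder by roulette
#'   draws proportional to `s_i` over the still-unselected configurable
#'   cells. High-quality but still stochastic, so sources differ.
#'
#' [initialize_population()] mixes the two: each of the `SN` sources uses the
#' pseudo-random method with probability `init_pseudo_prob`, otherwise the
#' complete-random one. Mixing trades initial quality against the diversity
#' the colony needs to escape local optima.
#'
#' All draws use R's global RNG stream; call `set.seed()` for reproducibility.
#'
#' @inheritParams objectives
#' @param best_fraction Fraction of `Q` placed greedily by score rank.
#' @return A logical solution matrix with exactly `Q` protected cells.
#' @examples
#' g <- suitability_grid(matrix(runif(100), 10, 10))
#' set.seed(1)
#' x <- init_pseudo_random(g, 10, zoning_weights(0.5, 0.5, 0))
#' sum(x)
#' @name initialization
NULL

#' @rdname initialization
#' @export
init_complete_random <- function(grid, Q) {
  grid <- check_grid(grid)
  Q <- check_quota(Q, grid)
  cand <- which(grid$configurable)
  pick <- if (length(cand) == Q) cand else cand[sample.int(length(cand), Q)]
  sol <- array(FALSE, dim(grid$eco))
  sol[pick] <- TRUE
  sol
}

#' @rdname initialization
#' @param weights Length-3 weights; only the two site weights enter the score.
#' @export
init_pseudo_random <- function(grid, Q, weights, best_fraction = 0.5) {
  grid <- check_grid(grid)
  Q <- check_quota(Q, grid)
  w <- check_weights(weights)
  if (best_fraction < 0 || best_fraction > 1)
    stop("`best_fraction` must be in [0, 1]", call. = FALSE)
  s <- site_score(grid, w)
  cand <- which(grid$configurable)
  key <- rm_order_key(grid$n_rows, grid$n_cols)[cand]

  n_greedy <- floor(best_fraction * Q)
  ord <- order(-s[cand], key)
  pick <- cand[ord[seq_len(n_greedy)]]

  n_rest <- Q - n_greedy
  if (n_rest > 0) {
    rest <- setdiff(cand, pick)
    p <- s[rest]
    pos <- sum(p > 0)
    if (pos == 0) {
      # degenerate score surface: fall back to a uniform draw
      pick <- c(pick, rest[sample.int(length(rest), n_rest)])
    } else if (pos >= n_rest) {
      pick <- c(pick, rest[sample.int(length(rest), n_rest, prob = p)])
    } else {
      # roulette can only ever reach positive-score cells; take them all,
      # then fill uniformly
      pz <- rest[p > 0]
      zz <- rest[p <= 0]
      pick <- c(pick, pz, zz[sample.int(length(zz), n_rest - pos)])
    }
  }
  sol <- array(FALSE, dim(grid$eco))
  sol[pick] <- TRUE
  sol
}

#' @rdname initialization
#' @param control An [abc_control()] list supplying `SN`, `Q`-independent
#'   initialization settings and the compactness window.
#' @return For `initialize_population()`: a list of `SN` food sources, each a
#'   list with elements `solution`, `fitness` and `trials` (initialized to 0).
#' @export
initialize_population <- function(grid, Q, weights, control = abc_control()) {
  grid <- check_grid(grid)
  Q <- check_quota(Q, grid)
  w <- check_weights(weights)
  lapply(seq_len(control$SN), function(i) {
    sol <- if (stats::runif(1) < control$init_pseudo_prob)
      init_pseudo_random(grid, Q, w, control$init_best_fraction)
    else
      init_complete_random(grid, Q)
    list(solution = sol,
         fitness = evaluate_fitness(sol, grid, w, Q, control$window),
         trials = 0L)
  })
}

#' Fitness-proportional (roulette-wheel) selection
#'
#' Draws one index with probability `fitness[j] / sum(fitness)`. With
#' all-zero fitness values the draw is uniform (documented fallback; cannot
#' occur for feasible solutions of the zoning objective with any positive
#' weight, but keeps the operation total).
#'
#' @param fitnesses Non-negative numeric vector.
#' @return A single integer index.
#' @export
roulette_select <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("fitness values must be >= 0", call. = FALSE)
  if (sum(fitnesses) <= 0)
    return(sample.int(length(fitnesses), 1))
  sample.int(length(fitnesses), 1, prob = fitnesses)
}
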
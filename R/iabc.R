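#' Control parameters for the bee colony optimizer
#'
#' @param SN Number of food sources (candidate solutions kept by the
#'   colony). Default 12.
#' @param limit Number of consecutive non-improving cycles after which a
#'   food source is abandoned and re-seeded by a scout. Default 150.
#' @param mcn Maximum number of cycles (iterations). Default 1000.
#' @param window Odd side length of the compactness neighborhood. Default 3.
#' @param init_pseudo_prob Probability that a food source (initial or
#'   scout-replaced) is built by the pseudo-random initializer rather than
#'   the complete-random one. Default 0.5.
#' @param init_best_fraction Fraction of `Q` placed greedily by site-score
#'   rank in the pseudo-random initializer. Default 0.5.
#' @param swap_range Integer `(low, high)` range for the number of exchanges
#'   attempted by the swap local search each cycle. Default `c(20, 40)`.
#' @param p_rect Probability of the rectangular replacement region (R1)
#'   versus the poor-quality region (R2). Default 0.5.
#' @param p_best_alter Probability of the best-position alteration (A1)
#'   versus the random one (A2). Default 0.5.
#' @return A list of class `"abc_control"`.
#' @export
abc_control <- function(SN = 12, limit = 150, mcn = 1000, window = 3,
                        init_pseudo_prob = 0.5, init_best_fraction = 0.5,
                        swap_range = c(20L, 40L),
                        p_rect = 0.5, p_best_alter = 0.5) {
  ctl <- list(SN = as.integer(SN), limit = as.integer(limit),
              mcn = as.integer(mcn), window = check_window(window),
              init_pseudo_prob = init_pseudo_prob,
              init_best_fraction = init_best_fraction,
              swap_range = as.integer(swap_range),
              p_rect = p_rect, p_best_alter = p_best_alter)
  if (ctl$SN < 2) stop("SN must be >= 2", call. = FALSE)
  if (ctl$limit < 1) stop("limit must be >= 1", call. = FALSE)
  if (ctl$mcn < 0) stop("mcn must be >= 0", call. = FALSE)
  for (p in c("init_pseudo_prob", "init_best_fraction",
              "p_rect", "p_best_alter"))
    if (ctl[[p]] < 0 || ctl[[p]] > 1)
      stop(p, " must be in [0, 1]", call. = FALSE)
  if (length(ctl$swap_range) != 2 || ctl$swap_range[1] > ctl$swap_range[2] ||
      ctl$swap_range[1] < 0)
    stop("swap_range must be non-negative (low, high) with low <= high",
         call. = FALSE)
  class(ctl) <- "abc_control"
  ctl
}

#' Zone protected ecological areas with an artificial bee colony
#'
#' Selects exactly `Q` configurable raster cells for protection, maximizing
#' `w1 * Ecological + w2 * (1 - Development) + w3 * Compactness` (see
#' [evaluate_fitness()]) with a discrete artificial bee colony. Each cycle:
#'
#' 1. *Employed phase*: every food source proposes a replace-and-alter
#'    neighbor (region copied from a random other source, quota restored by
#'    alteration; see [generate_neighbor()]); the better of source and
#'    neighbor is kept (greedy retention).
#' 2. *Onlooker phase*: selection probabilities are computed once from the
#'    current fitness values; `SN` onlookers each follow a roulette-selected
#'    source and apply the same neighbor-and-keep step to it.
#' 3. *Local search*: the cycle-best source is refined by the swap local
#'    search ([swap_local_search()]).
#' 4. *Scout phase*: any source not improved for `limit` consecutive cycles
#'    is replaced by a fresh mixed-initialization solution.
#' 5. The global best is updated; its fitness trace is non-decreasing.
#'
#' A source's trial counter resets to zero in any cycle where its fitness
#' strictly improves and increments by one otherwise.
#'
#' All randomness flows from R's global RNG; passing `seed` makes the run
#' bit-reproducible.
#'
#' @inheritParams objectives
#' @param Q Protection quota: the exact number of cells to protect.
#' @param control An [abc_control()] list.
#' @param seed Optional integer seed (applied with `set.seed()`).
#' @param verbose Print progress every 50 cycles.
#' @return An object of class `"abc_zoning"` with elements:
#'   `solution` (logical matrix, exactly `Q` protected cells), `fitness`,
#'   `objectives` (named ecological / development / compactness values of the
#'   best solution), `trace` (data frame with one row per cycle, including
#'   cycle 0: `iteration`, `best_fitness`, `ecological`, `development`,
#'   `compactness`, `scout_events`), `scout_events`, `degenerate_moves`,
#'   `population` (final food sources), `Q`, `weights`, `control`, `seed`,
#'   `call`.
#' @examples
#' g <- suitability_grid(matrix(runif(64), 8, 8))
#' fit <- zone_abc(g, Q = 8, weights = zoning_weights(0.34, 0.33, 0.33),
#'                 control = abc_control(SN = 4, mcn = 30), seed = 1)
#' fit
#' @seealso [density_slice()] for the deterministic baseline,
#'   [multipeak_surface()] for the synthetic validation landscape.
#' @export
zone_abc <- function(grid, Q, weights, control = abc_control(),
                     seed = NULL, verbose = FALSE) {
  grid <- check_grid(grid)
  Q <- check_quota(Q, grid)
  w <- check_weights(weights)
  if (!inherits(control, "abc_control"))
    stop("`control` must come from abc_control()", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cl <- match.call()
  ctl <- control
  SN <- ctl$SN

  new_source <- function() {
    sol <- if (stats::runif(1) < ctl$init_pseudo_prob)
      init_pseudo_random(grid, Q, w, ctl$init_best_fraction)
    else
      init_complete_random(grid, Q)
    st <- state_new(grid, sol, w, Q, ctl$window)
    list(st = st, x = as.logical(sol), fit = zb_fitness(st))
  }

  sources <- vector("list", SN)
  fits <- numeric(SN)
  trials <- integer(SN)
  for (j in seq_len(SN)) {
    sources[[j]] <- new_source()
    fits[j] <- sources[[j]]$fit
  }

  gbest_j <- which.max(fits)
  gbest <- list(x = sources[[gbest_j]]$x, fit = fits[gbest_j],
                parts = zb_parts(sources[[gbest_j]]$st))
  scout_events <- 0L
  degenerate_moves <- 0L
  trace <- matrix(NA_real_, ctl$mcn + 1L, 6L,
                  dimnames = list(NULL, c("iteration", "best_fitness",
                                          "ecological", "development",
                                          "compactness", "scout_events")))
  record <- function(it) {
    trace[it + 1L, ] <<- c(it, gbest$fit, gbest$parts[["ecological"]],
                           gbest$parts[["development"]],
                           gbest$parts[["compactness"]], scout_events)
  }
  record(0L)

  s_score <- site_score(grid, w)
  rm_key <- rm_order_key(grid$n_rows, grid$n_cols)

  # propose a neighbor for source j and keep it if strictly better
  try_improve <- function(j, improved) {
    k <- sample.int(SN - 1L, 1)
    if (k >= j) k <- k + 1L
    res <- neighbor_state(sources[[j]]$st, sources[[k]]$x,
                          sources[[j]]$x,
                          grid, w, Q, ctl$window, ctl$p_rect,
                          ctl$p_best_alter, s_score, rm_key)
    if (res$degenerate) {
      degenerate_moves <<- degenerate_moves + 1L
    } else if (res$fitness > fits[j]) {
      sources[[j]] <<- list(st = res$st, x = zb_x(res$st), fit = res$fitness)
      fits[j] <<- res$fitness
      improved[j] <- TRUE
    }
    improved
  }

  for (it in seq_len(ctl$mcn)) {
    improved <- logical(SN)

    for (j in seq_len(SN))                       # employed bees
      improved <- try_improve(j, improved)

    p <- if (sum(fits) > 0) fits / sum(fits) else rep(1 / SN, SN)
    for (o in seq_len(SN)) {                     # onlooker bees
      j <- sample.int(SN, 1, prob = p)
      improved <- try_improve(j, improved)
    }

    jb <- which.max(fits)                        # local search on lbest
    st2 <- zb_clone(sources[[jb]]$st)
    kept <- swap_state(st2, draw_swap_count(ctl$swap_range))
    if (kept > 0L) {
      f2 <- zb_fitness(st2)
      if (f2 > fits[jb]) {
        sources[[jb]] <- list(st = st2, x = zb_x(st2), fit = f2)
        fits[jb] <- f2
        improved[jb] <- TRUE
      }
    }

    trials <- ifelse(improved, 0L, trials + 1L)

    jb <- which.max(fits)                        # store global optimum
    if (fits[jb] > gbest$fit)
      gbest <- list(x = sources[[jb]]$x, fit = fits[jb],
                    parts = zb_parts(sources[[jb]]$st))

    for (j in seq_len(SN)) {                     # scout phase
      if (trials[j] >= ctl$limit) {
        sources[[j]] <- new_source()
        fits[j] <- sources[[j]]$fit
        trials[j] <- 0L
        scout_events <- scout_events + 1L
        if (fits[j] > gbest$fit)
          gbest <- list(x = sources[[j]]$x, fit = fits[j],
                        parts = zb_parts(sources[[j]]$st))
      }
    }

    record(it)
    if (verbose && it %% 50L == 0L)
      message(sprintf("cycle %d: best fitness %.6f", it, gbest$fit))
  }

  sol <- matrix(gbest$x, grid$n_rows, grid$n_cols)
  structure(list(
    solution = sol,
    fitness = gbest$fit,
    objectives = c(ecological = unname(gbest$parts[["ecological"]]),
                   development = unname(gbest$parts[["development"]]),
                   compactness = unname(gbest$parts[["compactness"]])),
    trace = as.data.frame(trace),
    scout_events = scout_events,
    degenerate_moves = degenerate_moves,
    population = lapply(seq_len(SN), function(j)
      list(solution = matrix(sources[[j]]$x, grid$n_rows, grid$n_cols),
           fitness = fits[j], trials = trials[j])),
    Q = Q, weights = w, control = ctl, seed = seed, call = cl),
    class = "abc_zoning")
}

#' @export
print.abc_zoning <- function(x, ...) {
  cat("Artificial bee colony zoning\n")
  cat("  quota Q:", x$Q, "cells;  weights:",
      paste(sprintf("%.3g", x$weights), collapse = " / "), "\n")
  cat(sprintf("  best fitness: %.6f after %d cycles\n",
              x$fitness, nrow(x$trace) - 1L))
  cat(sprintf("  sub-objectives: ecological %.4f, development %.4f, compactness %.4f\n",
              x$objectives[["ecological"]], x$objectives[["development"]],
              x$objectives[["compactness"]]))
  invisible(x)
}

#' @export
summary.abc_zoning <- function(object, ...) {
  tr <- object$trace
  structure(list(
    fitness = object$fitness,
    objectives = object$objectives,
    Q = object$Q,
    weights = object$weights,
    cycles = nrow(tr) - 1L,
    initial_fitness = tr$best_fitness[1],
    scout_events = object$scout_events,
    degenerate_moves = object$degenerate_moves,
    population_fitness = vapply(object$population, `[[`, 0, "fitness")),
    class = "summary.abc_zoning")
}

#' @export
print.summary.abc_zoning <- function(x, ...) {
  cat("Artificial bee colony zoning — summary\n")
  cat(sprintf("  cycles: %d   quota: %d cells\n", x$cycles, x$Q))
  cat(sprintf("  fitness: %.6f (initial best %.6f)\n",
              x$fitness, x$initial_fitness))
  cat(sprintf("  ecological %.4f | development %.4f | compactness %.4f\n",
              x$objectives[["ecological"]], x$objectives[["development"]],
              x$objectives[["compactness"]]))
  cat(sprintf("  scouts sent: %d   degenerate moves: %d\n",
              x$scout_events, x$degenerate_moves))
  cat("  final population fitness:",
      paste(sprintf("%.4f", sort(x$population_fitness, decreasing = TRUE)),
            collapse = " "), "\n")
  invisible(x)
}

#' Plot method for bee-colony zoning results
#'
#' `which = "trace"` draws the global-best fitness against the cycle number;
#' `which = "map"` draws the protection map (protected cells dark).
#'
#' @param x An `"abc_zoning"` object.
#' @param which `"trace"` or `"map"`.
#' @param ... Passed to the underlying base graphics call.
#' @export
plot.abc_zoning <- function(x, which = c("trace", "map"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot(x$trace$iteration, x$trace$best_fitness, type = "l",
         xlab = "cycle", ylab = "global best fitness", ...)
  } else {
    image(t(x$solution[nrow(x$solution):1, ]), useRaster = TRUE,
          col = c("grey92", "darkgreen"), axes = FALSE, asp = 1, ...)
  }
  invisible(x)
}
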
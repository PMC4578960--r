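# Shared fixtures and independent oracles.  Everything is generated in code;
# oracles deliberately use brute-force formulations, never the incremental
# machinery they are checking.

# 4x4 grid with simple enumerable values: eco = (row + col)/10, dev = row/10
tiny_grid <- function() {
  eco <- outer(1:4, 1:4, function(r, c) (r + c) / 10)
  dev <- outer(1:4, 1:4, function(r, c) r / 10)
  suitability_grid(eco, dev)
}

# random feasible solution with exactly Q protected configurable cells
rand_solution <- function(grid, Q) {
  cand <- which(grid$configurable)
  sol <- array(FALSE, dim(grid$eco))
  sol[sample(cand, Q)] <- TRUE
  sol
}

# brute-force fitness: direct sums and an explicit per-cell window loop
brute_fitness <- function(sol, grid, w, Q = sum(sol), window = 3) {
  h <- (window - 1) %/% 2
  com <- 0
  for (i in which(sol)) {
    r <- (i - 1) %% grid$n_rows + 1
    c <- (i - 1) %/% grid$n_rows + 1
    rows <- max(1, r - h):min(grid$n_rows, r + h)
    cols <- max(1, c - h):min(grid$n_cols, c + h)
    d <- sum(grid$configurable[rows, cols])
    com <- com + if (d > 0) sum(sol[rows, cols]) / d else 0
  }
  w[1] * sum(grid$eco[sol]) / Q + w[2] * (1 - sum(grid$dev[sol]) / Q) +
    w[3] * com / Q
}

# exhaustive optimum over all Q-subsets of configurable cells
enumerate_optimum <- function(grid, Q, w, window = 3) {
  cand <- which(grid$configurable)
  best <- -Inf; best_set <- NULL
  sets <- utils::combn(cand, Q)
  for (k in seq_len(ncol(sets))) {
    sol <- array(FALSE, dim(grid$eco))
    sol[sets[, k]] <- TRUE
    f <- brute_fitness(sol, grid, w, Q, window)
    if (f > best) { best <- f; best_set <- sets[, k] }
  }
  list(fitness = best, cells = best_set)
}

cells_rc <- function(i, grid) {
  cbind((i - 1) %% grid$n_rows + 1, (i - 1) %/% grid$n_rows + 1)
}
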
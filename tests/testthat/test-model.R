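test_that("site objectives are per-quota means with exact extremes", {
  eco <- matrix(0, 4, 4); eco[1, 1:3] <- 1
  g <- suitability_grid(eco, dev = 1 - eco)
  sel <- matrix(FALSE, 4, 4); sel[1, 1:3] <- TRUE

  expect_equal(evaluate_ecological(sel, g, 3), 1)
  expect_equal(evaluate_development(sel, g, 3), 0)

  other <- matrix(FALSE, 4, 4); other[3, 1:3] <- TRUE
  expect_equal(evaluate_ecological(other, g, 3), 0)
  expect_equal(evaluate_development(other, g, 3), 1)

  # hand-summed case on the enumerable grid: eco = (row+col)/10 at
  # (1,1), (2,3), (4,4) -> (0.2 + 0.5 + 0.8) / 3
  tg <- tiny_grid()
  sol <- matrix(FALSE, 4, 4)
  sol[cbind(c(1, 2, 4), c(1, 3, 4))] <- TRUE
  expect_equal(evaluate_ecological(sol, tg, 3), 0.5)
  expect_equal(evaluate_development(sol, tg, 3), (0.1 + 0.2 + 0.4) / 3)
})

test_that("site objectives equal direct summation on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    g <- random_instance(6, 6, 0.15)
    Q <- 8
    sol <- rand_solution(g, Q)
    expect_equal(evaluate_ecological(sol, g, Q), sum(g$eco[sol]) / Q)
    expect_equal(evaluate_development(sol, g, Q), sum(g$dev[sol]) / Q)
  }
})

test_that("solution validation rejects shape and feasibility violations", {
  g <- tiny_grid()
  expect_error(evaluate_ecological(matrix(FALSE, 3, 3), g, 1), "shape")
  sol <- matrix(FALSE, 4, 4); sol[1, 1] <- TRUE
  expect_error(evaluate_ecological(sol, g, 2), "Q = 2")
  gb <- suitability_grid(g$eco, g$dev,
                         configurable = matrix(c(FALSE, TRUE), 4, 4))
  expect_error(evaluate_ecological(sol, gb, 1), "non-configurable")
})

test_that("cell compactness counts protected over configurable in the window", {
  g <- suitability_grid(matrix(0.5, 5, 5))
  full <- matrix(TRUE, 5, 5)
  expect_equal(cell_compactness(full, g, c(3, 3)), 1)

  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  expect_equal(cell_compactness(lone, g, c(3, 3)), 1 / 9)

  # corner window truncates to 4 cells; 2 configurable, 1 protected
  conf <- matrix(TRUE, 5, 5)
  conf[1, 2] <- FALSE; conf[2, 1] <- FALSE   # window of (1,1): cells (1,1),(2,2) left
  gc <- suitability_grid(matrix(0.5, 5, 5), configurable = conf)
  sol <- matrix(FALSE, 5, 5); sol[1, 1] <- TRUE
  expect_equal(cell_compactness(sol, gc, c(1, 1)), 0.5)

  # fully blocked neighborhood is 0, not NaN
  g0 <- suitability_grid(matrix(0.5, 5, 5),
                         configurable = matrix(FALSE, 5, 5))
  expect_equal(cell_compactness(matrix(FALSE, 5, 5), g0, c(3, 3)), 0)

  expect_error(cell_compactness(lone, g, c(6, 1)), "outside the grid")
})

test_that("cell compactness is monotone in window protection", {
  g <- suitability_grid(matrix(0.5, 5, 5))
  sol <- matrix(FALSE, 5, 5); sol[3, 3] <- TRUE
  prev <- cell_compactness(sol, g, c(3, 3))
  for (cell in list(c(2, 2), c(2, 3), c(4, 4), c(3, 4))) {
    sol[cell[1], cell[2]] <- TRUE
    cur <- cell_compactness(sol, g, c(3, 3))
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("solution compactness matches the explicit window-count oracle", {
  g <- suitability_grid(matrix(0.5, 9, 9))
  # solid 3x4 block away from borders
  sol <- matrix(FALSE, 9, 9); sol[4:6, 3:6] <- TRUE
  per_cell <- vapply(which(sol), function(i)
    cell_compactness(sol, g, cells_rc(i, g)[1, ]), 0)
  expect_equal(evaluate_compactness(sol, g, 12), mean(per_cell))
  expect_lt(evaluate_compactness(sol, g, 12), 1)
  # interior cell of the block has a saturated window
  expect_equal(cell_compactness(sol, g, c(5, 4)), 1)

  # pairwise-isolated cells: each window holds only its center
  iso <- matrix(FALSE, 9, 9); iso[cbind(c(2, 2, 6, 6), c(2, 6, 2, 6))] <- TRUE
  expect_equal(evaluate_compactness(iso, g, 4), 1 / 9)

  # determinism
  expect_identical(evaluate_compactness(sol, g, 12),
                   evaluate_compactness(sol, g, 12))
})

test_that("fitness composes the three sub-objectives and stays in [0,1]", {
  g <- tiny_grid()
  sol <- matrix(FALSE, 4, 4); sol[2, 2:4] <- TRUE
  w <- zoning_weights(0.34, 0.33, 0.33)
  f <- evaluate_fitness(sol, g, w, 3)
  ref <- 0.34 * evaluate_ecological(sol, g, 3) +
    0.33 * (1 - evaluate_development(sol, g, 3)) +
    0.33 * evaluate_compactness(sol, g, 3)
  expect_equal(f, ref, tolerance = 1e-12)

  # degenerate weight corners
  eco1 <- matrix(0, 4, 4); eco1[1, 1:3] <- 1
  g2 <- suitability_grid(eco1, dev = eco1)
  sel <- matrix(FALSE, 4, 4); sel[1, 1:3] <- TRUE
  expect_equal(evaluate_fitness(sel, g2, c(1, 0, 0), 3), 1)
  expect_equal(evaluate_fitness(sel, g2, c(0, 1, 0), 3), 0)

  expect_error(evaluate_fitness(sol, g, c(0.5, 0.6, 0.1), 3), "sum to 1")

  set.seed(21)
  for (rep in 1:10) {
    gi <- random_instance(7, 7, 0.2)
    wi <- stats::runif(3); wi <- wi / sum(wi)
    si <- rand_solution(gi, 6)
    fi <- evaluate_fitness(si, gi, wi, 6)
    expect_gte(fi, 0); expect_lte(fi, 1)
    expect_equal(fi, brute_fitness(si, gi, wi, 6), tolerance = 1e-12)
  }
})

test_that("with no compactness weight the optimum is the top-Q site scores", {
  set.seed(31)
  g <- random_instance(4, 4, 0)
  w <- c(0.6, 0.4, 0)
  opt <- enumerate_optimum(g, 3, w)
  ds <- density_slice(g, 3, w)
  expect_equal(evaluate_fitness(ds, g, w, 3), opt$fitness, tolerance = 1e-12)
  expect_setequal(which(ds), opt$cells)
})

test_that("fitness_delta agrees with full recomputation", {
  set.seed(41)
  g <- random_instance(8, 8, 0.1)
  w <- c(0.4, 0.3, 0.3)
  Q <- 12
  for (rep in 1:100) {
    sol <- rand_solution(g, Q)
    off <- sample(which(sol), 1)
    on <- sample(which(!sol & g$configurable), 1)
    d <- fitness_delta(sol, g, w, cells_rc(off, g)[1, ], cells_rc(on, g)[1, ], Q)
    sol2 <- sol; sol2[off] <- FALSE; sol2[on] <- TRUE
    full <- evaluate_fitness(sol2, g, w, Q) - evaluate_fitness(sol, g, w, Q)
    expect_equal(d, full, tolerance = 1e-9)
  }

  # moving a worthless isolated cell into a high-value solid block must help
  eco <- matrix(0, 8, 8); eco[2:4, 2:4] <- 1
  gg <- suitability_grid(eco)
  sol <- matrix(FALSE, 8, 8); sol[2:4, 2:4] <- TRUE; sol[3, 3] <- FALSE
  sol[8, 8] <- TRUE
  d <- fitness_delta(sol, gg, w, c(8, 8), c(3, 3), 9)
  expect_gt(d, 0)

  # toggling a cell off and back on is a net zero
  st_off <- sol; st_off[8, 8] <- FALSE; st_off[2, 2] <- FALSE
  d0 <- fitness_delta(sol, gg, w, c(2, 2), c(3, 3), 9)
  d0b <- fitness_delta(sol, gg, w, c(2, 2), c(3, 3), 9)
  expect_identical(d0, d0b)
  expect_error(fitness_delta(sol, gg, w, c(1, 1), c(3, 3), 9),
               "not protected")
  expect_error(fitness_delta(sol, gg, w, c(8, 8), c(2, 2), 9),
               "already protected")
})
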
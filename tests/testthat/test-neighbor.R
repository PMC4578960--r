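test_that("rectangle replacement copies the region and nothing else", {
  set.seed(21)
  g <- random_instance(8, 8, 0)
  xj <- rand_solution(g, 10)
  xk <- rand_solution(g, 10)

  res <- replace_region_rect(xj, xk, g)
  inside <- res$region
  outside <- setdiff(seq_len(64), inside)
  expect_identical(res$solution[inside], xk[inside])
  expect_identical(res$solution[outside], xj[outside])

  # identical neighbor: idempotent whatever the rectangle
  for (i in 1:20) {
    res <- replace_region_rect(xj, xj, g)
    expect_identical(res$solution, xj)
  }
})

test_that("poor-quality regions pick the lowest-score protected cells", {
  g <- suitability_grid(matrix(1, 5, 5))
  w <- zoning_weights(0.5, 0.5, 0)
  xj <- matrix(FALSE, 5, 5); xj[2, 2:4] <- TRUE; xj[4, 2] <- TRUE
  xk <- xj

  # zero-size region leaves the solution untouched
  res <- replace_region_poor(xj, xk, g, w, size = 0)
  expect_identical(res$solution, xj)
  expect_length(res$region, 0)

  # identical neighbor: unchanged for any size
  res <- replace_region_poor(xj, xk, g, w, size = 3)
  expect_identical(res$solution, xj)

  # the unique zero-score protected cell must form the size-1 region
  eco <- matrix(1, 5, 5); eco[4, 2] <- 0
  g2 <- suitability_grid(eco)
  res <- replace_region_poor(xj, xk, g2, zoning_weights(1, 0, 0), size = 1)
  expect_equal(res$region, (2 - 1) * 5 + 4)  # linear index of (4,2)
})

test_that("alteration restores the quota exactly, in both strategies", {
  set.seed(22)
  g <- random_instance(8, 8, 0.1)
  w <- c(0.4, 0.3, 0.3)
  Q <- 12
  for (rep in 1:150) {
    xj <- rand_solution(g, Q)
    xk <- rand_solution(g, Q)
    res <- replace_region_rect(xj, xk, g)
    strat <- if (rep %% 2) "best" else "random"
    out <- alter_repair(res$solution, res$region, g, w, Q, strategy = strat)
    if (sum(res$solution) == Q) {
      expect_identical(out, res$solution)  # d = 0: returned as-is
    } else {
      expect_equal(sum(out), Q)
      expect_true(all(g$configurable[out]))
      # region cells were not altered
      expect_identical(out[res$region], res$solution[res$region])
    }
  }
})

test_that("best alteration removes the cell whose release helps most", {
  # one surplus protected cell; A1 must drop the outside protected cell with
  # the best exact objective improvement (brute-forced here)
  set.seed(23)
  g <- random_instance(7, 7, 0)
  w <- c(0.4, 0.3, 0.3)
  Q <- 8
  xj <- rand_solution(g, Q + 1)   # quota exceeded by one
  region <- which(xj)[1:2]        # pretend these two came from the neighbor
  out <- alter_repair(xj, region, g, w, Q, strategy = "best")
  dropped <- setdiff(which(xj), which(out))
  expect_length(dropped, 1)
  candidates <- setdiff(which(xj), region)
  deltas <- vapply(candidates, function(i) {
    x2 <- xj; x2[i] <- FALSE
    brute_fitness(x2, g, w, Q) - brute_fitness(xj, g, w, Q)
  }, 0)
  expect_equal(dropped, candidates[which.max(deltas)])
})

test_that("repair reverts when no eligible cell exists outside the region", {
  # deficit with every configurable cell inside the region: infeasible
  g <- suitability_grid(matrix(0.5, 3, 3))
  x <- matrix(FALSE, 3, 3)
  expect_null(alter_repair(x, seq_len(9), g, c(0.4, 0.3, 0.3), Q = 2))
})

test_that("generated neighbors are always feasible", {
  set.seed(24)
  g <- random_instance(8, 8, 0.1)
  w <- c(0.4, 0.3, 0.3)
  Q <- 10
  for (rep in 1:250) {
    xj <- rand_solution(g, Q)
    xk <- rand_solution(g, Q)
    v <- generate_neighbor(xj, xk, g, w, Q)
    expect_equal(sum(v), Q)
    expect_true(all(g$configurable[v]))
  }

  # no information to exchange
  xj <- rand_solution(g, Q)
  for (rep in 1:10)
    expect_true(all(generate_neighbor(xj, xj, g, w, Q) == xj))
})
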
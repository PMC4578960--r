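test_that("seeded runs are bit-reproducible", {
  g <- random_instance(10, 10, 0.1)  # instance fixed by the outer seed
  w <- zoning_weights(0.4, 0.3, 0.3)
  ctl <- abc_control(SN = 4, mcn = 20, limit = 10)
  a <- zone_abc(g, 12, w, ctl, seed = 99)
  b <- zone_abc(g, 12, w, ctl, seed = 99)
  expect_identical(a$solution, b$solution)
  expect_identical(a$trace, b$trace)
  expect_identical(a$fitness, b$fitness)
  c <- zone_abc(g, 12, w, ctl, seed = 100)
  expect_false(identical(a$solution, c$solution) &&
               identical(a$trace, c$trace))
})

test_that("a zero-cycle run returns the best initial food source", {
  set.seed(41)
  g <- random_instance(8, 8, 0)
  w <- zoning_weights(0.34, 0.33, 0.33)
  fit <- zone_abc(g, 8, w, abc_control(SN = 5, mcn = 0), seed = 5)
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(fit$trace$iteration, 0)
  pop_fit <- vapply(fit$population, `[[`, 0, "fitness")
  expect_equal(fit$fitness, max(pop_fit))
  expect_equal(fit$fitness,
               evaluate_fitness(fit$solution, g, w, 8), tolerance = 1e-9)
})

test_that("every retained solution is feasible and the trace is monotone", {
  set.seed(42)
  g <- random_instance(12, 12, 0.15)
  w <- zoning_weights(0.4, 0.3, 0.3)
  fit <- zone_abc(g, 20, w, abc_control(SN = 5, mcn = 40, limit = 8),
                  seed = 7)
  expect_equal(sum(fit$solution), 20)
  expect_true(all(g$configurable[fit$solution]))
  for (fs in fit$population) {
    expect_equal(sum(fs$solution), 20)
    expect_true(all(g$configurable[fs$solution]))
    expect_equal(fs$fitness, evaluate_fitness(fs$solution, g, w, 20),
                 tolerance = 1e-9)
  }
  expect_false(is.unsorted(fit$trace$best_fitness))
  expect_equal(fit$fitness, fit$trace$best_fitness[nrow(fit$trace)])
  expect_equal(fit$fitness, evaluate_fitness(fit$solution, g, w, 20),
               tolerance = 1e-9)
  expect_false(is.unsorted(fit$trace$scout_events))
})

test_that("stagnant sources are abandoned by scouts at the limit", {
  # quota = configurable count: every source is the forced solution, no move
  # can improve, so with limit = 1 each source is re-seeded every cycle
  g <- suitability_grid(matrix(0.5, 4, 4))
  w <- zoning_weights(0.4, 0.3, 0.3)
  fit <- zone_abc(g, 16, w, abc_control(SN = 3, mcn = 5, limit = 1),
                  seed = 1)
  expect_equal(fit$scout_events, 15)   # SN * mcn
  expect_true(all(fit$solution))
  expect_equal(diff(range(fit$trace$best_fitness)), 0)
})

test_that("configuration errors are caught before any iteration", {
  g <- suitability_grid(matrix(0.5, 4, 4))
  w <- zoning_weights(0.4, 0.3, 0.3)
  expect_error(zone_abc(g, 17, w), "exceeds")
  expect_error(zone_abc(g, 4, w, control = list(SN = 3)), "abc_control")
  expect_error(abc_control(SN = 1), "SN")
  expect_error(abc_control(swap_range = c(9, 3)), "swap_range")
  expect_error(abc_control(init_pseudo_prob = 1.4), "init_pseudo_prob")
})

test_that("the colony solves a tiny instance to the enumerated optimum", {
  set.seed(43)
  g <- random_instance(4, 4, 0)
  w <- c(0.4, 0.3, 0.3)
  opt <- enumerate_optimum(g, 3, w)
  hits <- 0L
  for (s in 1:5) {
    fit <- zone_abc(g, 3, w, abc_control(SN = 4, mcn = 60, limit = 20),
                    seed = 1000 + s)
    if (abs(fit$fitness - opt$fitness) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("print, summary and plot methods run", {
  set.seed(44)
  g <- random_instance(6, 6, 0)
  fit <- zone_abc(g, 5, zoning_weights(0.4, 0.3, 0.3),
                  abc_control(SN = 3, mcn = 5), seed = 2)
  expect_output(print(fit), "bee colony")
  expect_output(print(summary(fit)), "scouts sent")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, which = "trace"))
  expect_silent(plot(fit, which = "map"))
})
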
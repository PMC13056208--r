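test_that("shape pair and changeover value match hand evaluation", {
  for (t in 0:100) {
    dd <- eto_d_pair(t, 100)
    expect_equal(dd[["d2"]], -dd[["d1"]])
    expect_lte(abs(dd[["d1"]]), 0.1)
  }
  expect_equal(eto_d_pair(100, 100)[["d1"]], 0.1 * exp(-1))
  expect_equal(eto_d_pair(0, 100)[["d1"]], 0.1 * cos(50))

  # CM = 0.01 u (t/tmax)^tan(-1)
  expect_equal(eto_cm(100, 100, fixed_rng(1)), 0.01)
  expect_equal(eto_cm(50, 100, fixed_rng(1)), 0.01 * 0.5^tan(-1),
               tolerance = 1e-12)
  expect_equal(eto_cm(50, 100, fixed_rng(1)), 0.02944, tolerance = 1e-3)
  expect_equal(eto_cm(3, 10, fixed_rng(0)), 0)

  # with a fixed draw CM decreases strictly in t (negative exponent)
  cms <- vapply(1:100, function(t) eto_cm(t, 100, fixed_rng(0.7)),
                numeric(1))
  expect_true(all(diff(cms) < 0))
})

test_that("transition iteration and CE schedule follow the floor formulas", {
  expect_identical(eto_transition(100), 45L)
  expect_identical(eto_transition(10), 5L)
  expect_identical(eto_transition(1), 1L)

  expect_identical(eto_ce_first(100), 65L)
  expect_identical(eto_ce_first(50), 33L)
  # the recurrence explodes: the second event lands far beyond the budget
  expect_equal(eto_ce_next(65, 65, 100), 25937)
  expect_gt(eto_ce_next(65, 65, 100), 100)
})

test_that("CE bound adaptation matches stubbed substitution", {
  xb <- c(0.4, -0.2)
  xs <- c(0.1, 0.3)
  # t = tmax: both bounds collapse to zero
  b <- eto_ce_bounds(xb, xs, 100, 100, fixed_rng(rep(0.5, 4)))
  expect_equal(b$upper, c(0, 0))
  expect_equal(b$lower, c(0, 0))

  # r1 = 1, r2 = 0 (both pairs): UB = (1 - t/tmax) xb, LB = -same
  b <- eto_ce_bounds(xb, xs, 50, 100, fixed_rng(c(1, 0, 1, 0)))
  expect_equal(b$upper, 0.5 * xb)
  expect_equal(b$lower, -0.5 * xb)
  expect_false(b$ok) # xb[2] < 0 makes LB > UB there: event not applicable

  # coincident best pair: the |xb - xs| term vanishes
  b <- eto_ce_bounds(c(0.4, 0.2), c(0.4, 0.2), 50, 100,
                     fixed_rng(c(0.8, 0.9, 0.2, 0.9)))
  expect_equal(b$upper, 0.8 * 0.5 * c(0.4, 0.2))
  expect_equal(b$lower, -0.2 * 0.5 * c(0.4, 0.2))
  expect_true(b$ok)
})

test_that("weighting coefficients match hand values and identities", {
  # vanishing factor at t/tmax = 0.85, any draw
  expect_equal(eto_alpha1(85, 100, fixed_rng(0.33)), 0)
  expect_equal(eto_alpha3(85, 100, fixed_rng(0.77)), 0)
  # u = 1 at t = tmax
  expect_equal(eto_alpha1(100, 100, fixed_rng(1)), 0.45 * exp(-2))
  expect_equal(eto_alpha1(100, 100, fixed_rng(1)), 0.06090, tolerance = 1e-3)
  expect_equal(eto_alpha3(100, 100, fixed_rng(1)), 0.45 * exp(-0.3))
  expect_equal(eto_alpha3(100, 100, fixed_rng(1)), 0.33337, tolerance = 1e-4)
  # alpha2 formula with injected pair
  expect_equal(eto_alpha2(100, 100, fixed_rng(c(1, 1))),
               exp(tanh(1.5 * (-1 - 0.75) - 1)))
  # the diversity constant under the ratio guard
  expect_equal(eto_c_coef(), exp(tan(-1)))
  expect_equal(eto_c_coef(), 0.21068, tolerance = 1e-4)
  # alpha1 / alpha3 share the sign of (t/tmax - 0.85)
  for (t in c(10, 50, 84, 86, 100)) {
    s <- sign(t / 100 - 0.85)
    expect_equal(sign(eto_alpha1(t, 100, fixed_rng(0.5))), s)
    expect_equal(sign(eto_alpha3(t, 100, fixed_rng(0.5))), s)
  }
})

test_that("phase operators match straight-line hand computation", {
  xb <- 0.5
  xi <- 0.3
  # exploration phase 1: xb +/- u alpha1 |xb - xi|
  expect_equal(eto_explore1(xi, xb, 0.0609, fixed_rng(c(0.3, 1))), 0.51218)
  expect_equal(eto_explore1(xi, xb, 0.0609, fixed_rng(c(0.7, 1))), 0.48782)
  expect_equal(eto_explore1(xi, xb, 0, fixed_rng(c(0.2, 0.9))), xb)

  # exploration phase 2: xi +/- 3 u alpha2 |xb - xi|
  expect_equal(eto_explore2(xi, xb, 0.3784, fixed_rng(c(0.4, 1))), 0.52704)
  expect_equal(eto_explore2(xi, xb, 0.3784, fixed_rng(c(0.6, 1))), 0.07296)
  expect_equal(eto_explore2(xb, xb, 0.3784, fixed_rng(c(0.4, 1))), xb)

  # exploitation phase 1: xb +/- q4 alpha3 u |xb - xi|
  expect_equal(eto_exploit1(xi, xb, 0.33337, fixed_rng(c(0.3, 0.5, 1))),
               0.533337)
  expect_equal(eto_exploit1(xi, xb, 0.33337, fixed_rng(c(0.7, 0.5, 1))),
               0.466663)
  expect_equal(eto_exploit1(xi, xb, 0, fixed_rng(c(0.3, 0.5, 1))), xb)

  # exploitation phase 2: xi + c u alpha2 |xb - xi|
  expect_equal(eto_exploit2(xi, xb, 0.3784, 0.21065, fixed_rng(1)),
               0.3 + 0.21065 * 0.3784 * 0.2)
  expect_equal(eto_exploit2(xi, xb, 0.3784, 0.21065, fixed_rng(0)), xi)
  expect_equal(eto_exploit2(xb, xb, 0.3784, 0.21065, fixed_rng(1)), xb)
})

test_that("eto runs are elitist and seed-reproducible", {
  sp <- search_space(5, -5.12, 5.12)
  r1 <- eto_run(sphere, sp, n_pop = 10, tmax = 60, seed = 11)
  r2 <- eto_run(sphere, sp, n_pop = 10, tmax = 60, seed = 11)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$population, r2$population)
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  expect_equal(r1$best_fitness, min(r1$trace$best_fitness))
})
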
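test_that("selection shares normalize fitness and the threshold interpolates", {
  expect_equal(selection_probabilities(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  p <- selection_probabilities(runif(7) + 0.1)
  expect_equal(sum(p), 1)
  expect_equal(selection_probabilities(rep(2, 4)), rep(0.25, 4))
  expect_equal(selection_probabilities(rep(0, 4)), rep(0.25, 4))

  p <- c(0.2, 0.3, 0.5)
  expect_equal(selection_threshold(p, fixed_rng(0)), 0.2)
  expect_equal(selection_threshold(p, fixed_rng(1)), 0.5)
  expect_equal(selection_threshold(p, fixed_rng(0.5)), 0.35)
})

test_that("a short meto run matches the straight-line oracle exactly", {
  sp <- search_space(3, -1, 2)
  n <- 4
  values <- withr::with_seed(31, runif(600))
  res <- meto_run(sphere, sp, n_pop = n, tmax = 2,
                  params = meto_params(gls = gls_params(cmax = 3),
                                       gls_period = 1),
                  rng = fixed_rng(values))
  oracle <- straightline_meto(values, n = n, d = 3, lb = -1, ub = 2,
                              tmax = 2, objective = sphere,
                              gls_period = 1, cmax = 3)
  expect_lt(max(abs(res$population - oracle$x)), 1e-12)
  expect_lt(max(abs(res$fit - oracle$fit)), 1e-12)
  expect_lt(max(abs(res$trace$best_fitness - oracle$trace)), 1e-12)
  expect_lt(max(abs(res$best - oracle$xb)), 1e-12)
  expect_true(all(res$branches$gls_fired))
})

test_that("degenerate hybrid modes reduce to their parents", {
  sp <- search_space(4, -5.12, 5.12)
  # AOA branch off: bit-identical to an ETO run on the same draw stream
  m <- meto_run(sphere, sp, n_pop = 6, tmax = 30, rng = new_rng(17),
                rp_override = -Inf, gls = FALSE)
  e <- eto_run(sphere, sp, n_pop = 6, tmax = 30, rng = new_rng(17))
  expect_identical(m$trace$best_fitness, e$trace$best_fitness)
  expect_identical(m$population, e$population)
  expect_identical(m$best, e$best)
  expect_equal(sum(m$branches$n_aoa), 0)

  # AOA branch forced on: every update is an AOA operator
  m2 <- meto_run(sphere, sp, n_pop = 6, tmax = 30, rng = new_rng(17),
                 rp_override = Inf, gls = FALSE)
  expect_true(all(m2$branches$n_aoa == 6))
})

test_that("branch counts partition the population and traces reproduce", {
  sp <- search_space(3, 0, 1)
  r1 <- meto_run(sphere, sp, n_pop = 8, tmax = 40, seed = 5)
  r2 <- meto_run(sphere, sp, n_pop = 8, tmax = 40, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(r1$branches$n_aoa + r1$branches$n_eto == 8))
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  # guidance can only fire at multiples of the period
  fired_at <- r1$branches$iter[r1$branches$gls_fired]
  expect_true(all(fired_at %% 10 == 0))
})

test_that("the optimizer registry swaps algorithms by name", {
  expect_setequal(list_optimizers(), c("aoa", "eto", "meto"))
  fn <- get_optimizer("METO")
  sp <- search_space(2, 0, 1)
  res <- fn(sphere, sp, n_pop = 4, tmax = 5, seed = 1)
  expect_s3_class(res, "optim_result")
  expect_error(get_optimizer("nope"), "unknown optimizer")
  register_optimizer("dummy", function(objective, space, ...) "ok")
  expect_equal(get_optimizer("dummy")(sphere, sp), "ok")
  rm("dummy", envir = metoselect:::.optimizers)
})
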
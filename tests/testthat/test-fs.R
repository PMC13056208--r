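test_that("binarization thresholds, repairs, and replays the literal rule", {
  cfg <- fs_config()
  expect_equal(binarize(c(0.7, 0.2, 0.5), cfg), c(1L, 0L, 0L))
  expect_equal(binarize(c(0.9, 0.9), cfg), c(1L, 1L))
  # all-zero masks force the largest position coordinate on
  expect_equal(binarize(c(0.1, 0.2), cfg), c(0L, 1L))

  lit <- fs_config(binarization = "literal-random")
  expect_equal(binarize(c(0.9, 0.9), lit, fixed_rng(c(0.4, 0.6))),
               c(1L, 0L))
  expect_error(binarize(c(0.9, 0.9), lit), "draw stream")
})

test_that("knn error separates blobs and sits at chance under null labels", {
  # widely separated blobs: the informative features give zero error
  dat <- fs_data(make_blob_data(n = 200, d = 6, d_inf = 2, delta = 10))
  mask <- c(1L, 1L, 0L, 0L, 0L, 0L)
  expect_equal(knn_error(dat, mask), 0)

  # permuted labels: error near one half
  null <- make_blob_data(n = 400, d = 6, d_inf = 2, delta = 0, seed = 5)
  err <- knn_error(fs_data(null), rep(1L, 6))
  expect_gt(err, 0.5 - 0.12)
  expect_lt(err, 0.5 + 0.12)
})

test_that("knn prediction is deterministic with index tie-breaking", {
  x_train <- matrix(c(0, 0, 1, 1, 2), ncol = 1)
  y_train <- c(0L, 1L, 0L, 1L, 1L)
  # query at 0: neighbours sorted by distance then index
  pred <- knn_predict(x_train, y_train, matrix(0, 1, 1), k = 3)
  # rows 1, 2 (d = 0) then row 3 (d = 1, beats row 4 only by... equal: index)
  expect_equal(pred$score, mean(c(0L, 1L, 0L)))
  expect_equal(pred$class, 0L) # vote tie impossible at odd k; strict majority
  pred2 <- knn_predict(x_train, y_train, matrix(0, 1, 1), k = 5)
  expect_equal(pred2$score, 0.6)
  expect_equal(pred2$class, 1L)
})

test_that("the fitness composes error and sparsity as specified", {
  dat <- fs_data(make_blob_data(n = 150, d = 8, d_inf = 2, delta = 2))
  r <- new_rng(12)
  for (rep in 1:8) {
    position <- rng_unif(r, 8)
    cfg <- fs_config()
    f <- fs_fitness(dat, position, cfg)
    mask <- binarize(position, cfg)
    gamma <- knn_error(dat, mask, cfg)
    expect_equal(f, 0.99 * gamma + 0.01 * sum(mask) / 8)
    expect_gte(f, 0)
    expect_lte(f, 1)
    # boundary cases of the balance factor
    expect_equal(fs_fitness(dat, position, fs_config(rho = 1)), gamma)
    expect_equal(fs_fitness(dat, position, fs_config(rho = 0)),
                 sum(mask) / 8)
  }
})

test_that("test-split evaluation matches the metrics module", {
  dat <- make_blob_data(n = 200, d = 6, d_inf = 2, delta = 10)
  m <- evaluate_on_test(dat, c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$n_features, 2L)

  # metrics agree with confusion + compute_metrics on the exported counts
  prep <- fs_data(dat)
  mask <- c(1L, 0L, 1L, 0L, 1L, 0L)
  pred <- knn_predict(prep$x_train[, c(1, 3, 5)], prep$y_train,
                      prep$x_test[, c(1, 3, 5)], 5)
  expect_equal(
    evaluate_on_test(dat, mask)$accuracy,
    compute_metrics(confusion(prep$y_test, pred$class))$accuracy
  )
})

test_that("experiments aggregate runs into mean/std/best/worst", {
  dat <- make_blob_data(n = 120, d = 10, d_inf = 3, delta = 3)
  exp1 <- fs_experiment(dat, "meto", seeds = 7, n_pop = 6, tmax = 8)
  s <- exp1$summary
  expect_equal(s$mean, s$best)
  expect_equal(s$mean, s$worst)
  expect_true(all(s$std == 0))

  exp2 <- fs_experiment(dat, "aoa", seeds = c(1, 2), n_pop = 6, tmax = 8)
  acc <- exp2$runs$accuracy
  srow <- exp2$summary[exp2$summary$metric == "accuracy", ]
  expect_equal(srow$mean, mean(acc))
  expect_equal(srow$std, sqrt(mean((acc - mean(acc))^2)))
  nrow_feat <- exp2$summary[exp2$summary$metric == "n_features", ]
  expect_equal(nrow_feat$best, min(exp2$runs$n_features))

  # elitism carried through: final fitness never above the first trace point
  fit1 <- exp2$fits[[1]]
  expect_lte(fit1$fitness, fit1$result$trace$best_fitness[1])
})

test_that("results round-trip through the results directory bit-identically", {
  dat <- make_blob_data(n = 120, d = 8, d_inf = 2, delta = 3)
  exp1 <- fs_experiment(dat, "meto", seeds = 1:2, n_pop = 5, tmax = 6)
  dir <- withr::local_tempdir()
  paths <- write_results(exp1, dir)
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(exp1$summary))
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$algorithm, "meto")
  expect_length(meta$selected, 2)
})

test_that("invalid tables are rejected with informative errors", {
  dat <- make_blob_data(n = 60, d = 4, d_inf = 2, delta = 2)
  expect_error(fs_data(dplyr::select(dat, -label)), "label")
  bad <- dat
  bad$split[bad$split == "test"] <- "train"
  expect_error(fs_data(bad), "both classes")
  bad2 <- dat
  bad2$f1[1] <- NA
  expect_error(fs_data(bad2), "missing")
})
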
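test_that("connectivity matrices behave like correlations", {
  r <- new_rng(2)
  base <- matrix(rng_norm(r, 200 * 3), ncol = 3)
  ts <- cbind(base, base[, 1], -base[, 2]) # duplicate and negated ROIs
  fc <- pearson_fc(ts)
  expect_equal(fc[1, 4], 1)
  expect_equal(fc[2, 5], -1)
  expect_equal(fc, t(fc))
  expect_true(all(diag(fc) == 1))

  # independent long white-noise columns decorrelate
  wn <- matrix(rng_norm(r, 2000 * 4), ncol = 4)
  fcw <- pearson_fc(wn)
  off <- fcw[upper.tri(fcw)]
  expect_true(all(abs(off) < 3 / sqrt(2000)))

  # zero-variance ROI: flagged, correlation reported as 0
  flat <- cbind(base, 1)
  expect_warning(fcf <- pearson_fc(flat), "zero-variance")
  expect_equal(fcf[1, 4], 0)
  expect_error(pearson_fc(matrix(1:4, 2, 2)), "3 time points")
})

test_that("upper-triangle vectorization has the right length and order", {
  for (r in c(2, 5, 17, 116, 200)) {
    fc <- diag(r)
    expect_length(flatten_upper(fc), r * (r - 1) / 2)
  }
  # row-major order of the strict upper triangle
  m <- matrix(0, 3, 3)
  m[1, 2] <- 12
  m[1, 3] <- 13
  m[2, 3] <- 23
  m <- m + t(m)
  diag(m) <- 1
  expect_equal(flatten_upper(m), c(12, 13, 23))
  fc2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(flatten_upper(fc2), 0.4)
  expect_error(flatten_upper(matrix(0, 2, 3)), "square")
})

test_that("fisher scores rank separation and ignore translations", {
  r <- new_rng(9)
  n <- 300
  y <- rep(0:1, each = n / 2)
  x <- matrix(rng_norm(r, n * 5), ncol = 5)
  x[y == 1, 1] <- x[y == 1, 1] + 10 # one strongly informative feature
  s <- fisher_score(x, y)
  expect_gt(s[1], 15) # Delta = 10, unit variances: score = Delta^2/4 = 25
  expect_true(all(s[1] > 10 * s[2:5]))
  expect_equal(fisher_score(x + 100, y), s)
  # identical class distributions score near zero
  expect_lt(max(s[2:5]), 0.1)
  expect_error(fisher_score(x, rep(1, n)), "both classes")
})

test_that("the top-fraction filter uses the floor rule with stable ties", {
  expect_length(filter_top_fraction(runif(6670), 0.15), 1000)
  expect_length(filter_top_fraction(runif(19900), 0.15), 2985)
  expect_equal(filter_top_fraction(c(5, 1, 5, 2), 0.5), c(1, 3))
  expect_equal(filter_top_fraction(1:10, 1), 1:10)

  # planted features always beat noise at Delta >= 3 sigma
  for (seed in 1:5) {
    dat <- gen_feature_dataset(n = 200, d = 40, d_inf = 6, delta = 3,
                               seed = seed)
    x <- as.matrix(dat[paste0("f", 1:40)])
    s <- fisher_score(x, dat$label)
    expect_setequal(filter_top_fraction(s, 6 / 40), 1:6)
  }
})

test_that("ssdae pre-training reduces reconstruction loss deterministically", {
  r <- new_rng(14)
  x <- matrix(rng_norm(r, 200 * 60), ncol = 60)
  cfg <- ssdae_config(hidden = c(40, 20), epochs = c(15, 15), lr = 0.05,
                      batch_size = 50)
  fit <- pretrain_ssdae(x, cfg, new_rng(3))
  expect_lt(tail(fit$loss_traces[[1]], 1), fit$loss_traces[[1]][1])
  expect_lt(tail(fit$loss_traces[[2]], 1), fit$loss_traces[[2]][1])
  expect_equal(dim(fit$layers[[1]]$w), c(60, 40))
  expect_equal(dim(fit$layers[[2]]$w), c(40, 20))

  # bit-identical under the same stream seed
  fit2 <- pretrain_ssdae(x, cfg, new_rng(3))
  expect_identical(fit$layers, fit2$layers)

  # identity-learning limit: no noise, no sparsity, ample capacity
  xs <- matrix(rng_norm(r, 150 * 5), ncol = 5)
  cfg_id <- ssdae_config(hidden = c(30, 8), noise = 0, sparsity_weight = 0,
                         dropout = 0, epochs = c(300, 10), lr = 0.3,
                         batch_size = 150)
  fit_id <- pretrain_ssdae(xs, cfg_id, new_rng(4))
  expect_lt(tail(fit_id$loss_traces[[1]], 1),
            0.15 * fit_id$loss_traces[[1]][1])
})

test_that("mlp fine-tuning learns separable labels from ssdae weights", {
  dat <- make_blob_data(n = 200, d = 12, d_inf = 4, delta = 4, seed = 6)
  x <- as.matrix(dat[paste0("f", 1:12)])
  y <- dat$label
  scfg <- ssdae_config(hidden = c(10, 6), epochs = c(20, 20), lr = 0.05,
                       batch_size = 50)
  stack <- pretrain_ssdae(x, scfg, new_rng(1))
  mcfg <- mlp_config(hidden = c(10, 6, 4), epochs = 60, lr = 0.1,
                     batch_size = 20, dropout = 0.1)
  model <- finetune_mlp(x, y, stack, mcfg, new_rng(2))
  expect_lt(tail(model$loss_trace, 1), model$loss_trace[1])
  acc <- mean(predict(model, x, type = "class") == y)
  expect_gte(acc, 0.95)

  model2 <- finetune_mlp(x, y, stack, mcfg, new_rng(2))
  expect_identical(model$weights, model2$weights)

  # shape mismatches are rejected
  bad <- mlp_config(hidden = c(9, 6, 4))
  expect_error(finetune_mlp(x, y, stack, bad, new_rng(2)), "do not match")
})

test_that("learned-feature extraction is a deterministic row-wise map", {
  dat <- make_blob_data(n = 80, d = 10, d_inf = 3, delta = 3, seed = 3)
  x <- as.matrix(dat[paste0("f", 1:10)])
  stack <- pretrain_ssdae(x, ssdae_config(hidden = c(8, 5),
                                          epochs = c(5, 5)), new_rng(1))
  model <- finetune_mlp(x, dat$label, stack,
                        mlp_config(hidden = c(8, 5, 3), epochs = 5),
                        new_rng(2))
  lf <- extract_learned_features(model, x)
  expect_equal(dim(lf), c(80, 3))
  expect_identical(lf, extract_learned_features(model, x))
  perm <- sample(80)
  expect_equal(extract_learned_features(model, x[perm, ]), lf[perm, ])
})

test_that("the reduced full stack runs end-to-end", {
  ts <- gen_roi_timeseries(n_subjects = 60, r = 20, t_len = 120,
                           coupling_delta = 0.6, seed = 8)
  fc <- connectivity_features(ts)
  expect_equal(ncol(fc) - 2, 20 * 19 / 2) # features + label + subject_id
  learned <- learn_features(
    fc, fraction = 0.2,
    ssdae = ssdae_config(hidden = c(12, 6), epochs = c(10, 10)),
    mlp = mlp_config(hidden = c(12, 6, 4), epochs = 15),
    seed = 2
  )
  expect_equal(sum(startsWith(names(learned), "lf")), 4)
  expect_true(all(c("label", "split", "subject_id") %in% names(learned)))
  # the coupled-pair connectivity survives the Fisher filter
  expect_true("fc1" %in% attr(learned, "kept"))
})
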
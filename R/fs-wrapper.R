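# Binary wrapper feature selection over any registered optimizer.
# A continuous position in [0,1]^D is binarized into a feature mask, scored
# by the validation error of a deterministic K-nearest-neighbour classifier
# plus a feature-ratio penalty, and the optimizer minimizes that cost; the
# final mask is evaluated once on the held-out test split.

#' Feature-selection configuration
#'
#' The fitness is `rho * gamma + (1 - rho) * n_selected / D`, where `gamma`
#' is the validation misclassification rate of a KNN classifier (`k = 5`).
#' `rho = 0.99` lets the error dominate (standard wrapper practice).
#' Binarization defaults to thresholding the position at 0.5 -- the only
#' reading under which the fitness feeds back into the search; the
#' position-independent coin-flip rule is available as `"literal-random"`
#' for fidelity experiments.
#'
#' @param rho Error/sparsity balance in `[0, 1]`, default 0.99.
#' @param k KNN neighbourhood size (odd), default 5.
#' @param binarization `"threshold"` (default) or `"literal-random"`.
#' @param threshold Binarization threshold, default 0.5.
#' @return A list of class `fs_config`.
#' @export
fs_config <- function(rho = 0.99, k = 5,
                      binarization = c("threshold", "literal-random"),
                      threshold = 0.5) {
  binarization <- match.arg(binarization)
  stopifnot(rho >= 0, rho <= 1, k >= 1, k %% 2 == 1,
            threshold > 0, threshold < 1)
  structure(list(rho = rho, k = as.integer(k), binarization = binarization,
                 threshold = threshold),
            class = "fs_config")
}

#' Validate and prepare a labelled feature table
#'
#' Checks the contract of the wrapper: a data frame with numeric feature
#' columns, a binary `label` column (1 = positive class) and a `split`
#' column (`train`/`validation`/`test`, every split containing both
#' classes, no missing values), and caches per-split matrices.
#'
#' @param data A data frame as produced by [gen_feature_dataset()] or read
#'   with [read_feature_table()].
#' @return An object of class `fs_data`.
#' @export
fs_data <- function(data) {
  if (inherits(data, "fs_data")) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  if (!all(c("label", "split") %in% names(data))) {
    stop("data must contain 'label' and 'split' columns", call. = FALSE)
  }
  feat_cols <- setdiff(names(data), c("label", "split"))
  if (length(feat_cols) < 1) {
    stop("no feature columns found", call. = FALSE)
  }
  x <- as.matrix(data[feat_cols])
  if (!is.numeric(x) || anyNA(x)) {
    stop("feature columns must be numeric with no missing values",
         call. = FALSE)
  }
  label <- as.integer(data$label)
  stopifnot(all(label %in% 0:1))
  split <- as.character(data$split)
  if (!all(split %in% c("train", "validation", "test"))) {
    stop("split values must be train/validation/test", call. = FALSE)
  }
  out <- list(d = ncol(x), feature_names = feat_cols)
  for (s in c("train", "validation", "test")) {
    rows <- split == s
    if (length(unique(label[rows])) < 2) {
      stop("split '", s, "' does not contain both classes", call. = FALSE)
    }
    out[[paste0("x_", s)]] <- x[rows, , drop = FALSE]
    out[[paste0("y_", s)]] <- label[rows]
  }
  structure(out, class = "fs_data")
}

#' Deterministic K-nearest-neighbour prediction
#'
#' Euclidean distances; neighbour ties are broken by the lower training-row
#' index and vote ties toward the negative class (a strict majority of the
#' `k` votes is required for a positive call). The score is the positive
#' fraction among the `k` neighbours, the only calibration-free score a KNN
#' provides (and the score used for AUC).
#'
#' @param x_train,y_train Training matrix and 0/1 labels.
#' @param x_new Matrix of query rows.
#' @param k Neighbourhood size.
#' @return List with `class` (integer 0/1) and `score` (numeric).
#' @export
knn_predict <- function(x_train, y_train, x_new, k = 5) {
  stopifnot(nrow(x_train) >= k, ncol(x_train) == ncol(x_new))
  d2 <- outer(rowSums(x_new^2), rep(1, nrow(x_train))) +
    outer(rep(1, nrow(x_new)), rowSums(x_train^2)) -
    2 * tcrossprod(x_new, x_train)
  score <- apply(d2, 1, function(row) mean(y_train[order(row)[seq_len(k)]]))
  list(class = as.integer(score > 0.5), score = as.numeric(score))
}

#' Binarize a continuous position into a feature mask
#'
#' Threshold mode (default): feature `j` is selected iff
#' `position[j] > threshold`. Literal-random mode: selected iff a fresh
#' uniform draw is below 0.5, independent of the position. An all-zero mask
#' is repaired by forcing the coordinate with the largest position value to
#' 1, so the KNN fitness is always defined.
#'
#' @param position Numeric vector in `[0, 1]^D`.
#' @param config [fs_config()].
#' @param rng Draw stream (required in literal-random mode).
#' @return Integer 0/1 vector with at least one 1.
#' @export
binarize <- function(position, config = fs_config(), rng = NULL) {
  bx <- if (config$binarization == "threshold") {
    as.integer(position > config$threshold)
  } else {
    if (is.null(rng)) {
      stop("literal-random binarization needs a draw stream", call. = FALSE)
    }
    as.integer(rng_unif(rng, length(position)) < 0.5)
  }
  if (sum(bx) == 0) {
    bx[which.max(position)] <- 1L
  }
  bx
}

#' KNN validation error of a feature mask
#'
#' Misclassification rate on the validation split of a `k`-NN classifier
#' fit on the train split restricted to the masked features.
#'
#' @param data An [fs_data()] (or raw data frame).
#' @param mask Integer 0/1 mask with at least one selected feature.
#' @param config [fs_config()].
#' @return Error rate in `[0, 1]`.
#' @export
knn_error <- function(data, mask, config = fs_config()) {
  data <- fs_data(data)
  sel <- which(mask == 1)
  stopifnot(length(sel) >= 1)
  pred <- knn_predict(data$x_train[, sel, drop = FALSE], data$y_train,
                      data$x_validation[, sel, drop = FALSE], config$k)
  mean(pred$class != data$y_validation)
}

#' Wrapper fitness of a continuous position
#'
#' Binarize, measure the validation KNN error `gamma`, and combine:
#' `rho * gamma + (1 - rho) * n_selected / D`. A cost in `[0, 1]`,
#' minimized by the optimizer.
#'
#' @inheritParams knn_error
#' @param position Numeric vector in `[0, 1]^D`.
#' @param rng Draw stream (only needed for literal-random binarization).
#' @return Scalar fitness.
#' @export
fs_fitness <- function(data, position, config = fs_config(), rng = NULL) {
  data <- fs_data(data)
  mask <- binarize(position, config, rng)
  gamma <- knn_error(data, mask, config)
  config$rho * gamma + (1 - config$rho) * sum(mask) / data$d
}

#' Evaluate a feature mask on the test split
#'
#' Fits the KNN on the masked training features, predicts the test split
#' once, and reports accuracy, sensitivity, precision, F-score, rank-based
#' AUC (positive-neighbour-fraction scores) and the selected-feature count.
#'
#' @inheritParams knn_error
#' @return One-row tibble of metrics.
#' @export
evaluate_on_test <- function(data, mask, config = fs_config()) {
  data <- fs_data(data)
  sel <- which(mask == 1)
  stopifnot(length(sel) >= 1)
  pred <- knn_predict(data$x_train[, sel, drop = FALSE], data$y_train,
                      data$x_test[, sel, drop = FALSE], config$k)
  metrics <- compute_metrics(confusion(data$y_test, pred$class))
  metrics$auc <- auc_rank(pred$score, data$y_test)
  metrics$n_features <- length(sel)
  metrics
}

#' Select features with a metaheuristic wrapper
#'
#' Runs the named optimizer over `[0, 1]^D` with the KNN-error fitness,
#' binarizes the best position, and evaluates the resulting mask once on
#' the test split.
#'
#' @param data A labelled, split feature table (see [fs_data()]).
#' @param algorithm Registered optimizer name (`"meto"`, `"eto"`, `"aoa"`,
#'   or anything added via [register_optimizer()]).
#' @param n_pop Population size.
#' @param tmax Iteration budget.
#' @param config [fs_config()].
#' @param seed Integer seed for the run.
#' @param ... Passed to the optimizer run function.
#' @return An object of class `fs_fit`: list with `mask`, `selected`
#'   (feature names), `metrics` (test tibble), `fitness` (best fitness),
#'   `result` (the `optim_result`), `algorithm`, `seed`.
#' @examples
#' dat <- gen_feature_dataset(n = 120, d = 12, d_inf = 4, delta = 2, seed = 1)
#' fit <- select_features(dat, "meto", n_pop = 8, tmax = 10, seed = 1)
#' fit$metrics
#' @export
select_features <- function(data, algorithm = "meto", n_pop = 20,
                            tmax = 100, config = fs_config(), seed = 1,
                            ...) {
  data <- fs_data(data)
  run <- get_optimizer(algorithm)
  space <- search_space(data$d, 0, 1)
  objective <- function(position) fs_fitness(data, position, config)
  res <- run(objective, space, n_pop = n_pop, tmax = tmax,
             rng = new_rng(seed), ...)
  mask <- binarize(res$best, config)
  structure(
    list(
      mask = mask,
      selected = data$feature_names[mask == 1],
      metrics = evaluate_on_test(data, mask, config),
      fitness = res$best_fitness,
      result = res,
      algorithm = algorithm,
      seed = seed,
      config = config
    ),
    class = "fs_fit"
  )
}

#' @export
print.fs_fit <- function(x, ...) {
  cat("<fs_fit:", x$algorithm, "> seed", x$seed, "-", sum(x$mask),
      "features selected, fitness", format(x$fitness, digits = 6), "\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname tidy.fs_experiment
#' @method glance fs_fit
#' @export
glance.fs_fit <- function(x, ...) {
  dplyr::mutate(x$metrics, algorithm = x$algorithm, seed = x$seed,
                fitness = x$fitness, .before = 1)
}

#' Multi-seed feature-selection experiment
#'
#' Repeats [select_features()] over a vector of seeds and aggregates every
#' metric (and the selected-feature count) into Mean / StD / Best / Worst
#' rows, StD with the population (1/n) convention. For the feature count,
#' best is the minimum.
#'
#' @inheritParams select_features
#' @param seeds Integer vector of run seeds.
#' @return An object of class `fs_experiment` with `runs` (per-seed tibble),
#'   `summary` (metric-by-statistic tibble) and `fits` (list of `fs_fit`).
#' @export
fs_experiment <- function(data, algorithm = "meto", seeds = 1:10,
                          n_pop = 20, tmax = 100, config = fs_config(),
                          ...) {
  stopifnot(length(seeds) >= 1)
  data <- fs_data(data)
  fits <- lapply(seeds, function(s) {
    select_features(data, algorithm, n_pop = n_pop, tmax = tmax,
                    config = config, seed = s, ...)
  })
  runs <- dplyr::bind_rows(lapply(fits, glance))
  metrics <- c("accuracy", "sensitivity", "precision", "fscore", "auc",
               "n_features", "fitness")
  summary <- dplyr::bind_rows(lapply(metrics, function(m) {
    dplyr::mutate(
      aggregate_runs(runs[[m]],
                     higher_is_better = !m %in% c("n_features", "fitness")),
      metric = m, .before = 1
    )
  }))
  structure(
    list(runs = runs, summary = summary, fits = fits,
         algorithm = algorithm, seeds = seeds, config = config),
    class = "fs_experiment"
  )
}

#' @export
print.fs_experiment <- function(x, ...) {
  cat("<fs_experiment:", x$algorithm, ">", length(x$seeds), "runs\n")
  print(x$summary)
  invisible(x)
}

#' Tidy feature-selection results
#'
#' `tidy()` on an `fs_experiment` returns the per-run metric tibble;
#' `glance()` the aggregated summary in long metric-by-statistic form.
#' `glance()` on a single `fs_fit` returns its one-row metric record.
#'
#' @param x An `fs_experiment` (or `fs_fit` for `glance`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fs_experiment
#' @export
tidy.fs_experiment <- function(x, ...) x$runs

#' @rdname tidy.fs_experiment
#' @method glance fs_experiment
#' @export
glance.fs_experiment <- function(x, ...) {
  dplyr::mutate(x$summary, algorithm = x$algorithm, .before = 1)
}

#' Plot experiment metrics across runs
#'
#' One panel per metric with per-seed points and the run mean.
#'
#' @param object An `fs_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_experiment
#' @export
autoplot.fs_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$runs,
    cols = c("accuracy", "sensitivity", "precision", "fscore", "auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6,
                         colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "test-set value",
                  title = paste("Feature selection:", object$algorithm)) +
    ggplot2::theme_minimal()
}

#' Read / write feature tables and results
#'
#' `read_feature_table()` reads a CSV/TSV with a header row, a `label`
#' column and an optional `split` column; when `split` is absent a
#' stratified assignment is drawn with the given fractions and seed.
#' `write_results()` writes the experiment summary CSV and a JSON metadata
#' file (seeds, config, selected feature names per run).
#'
#' @param path Input file (`.csv` or `.tsv`).
#' @param split_fractions Used when the table has no `split` column.
#' @param seed Seed for the drawn split.
#' @return `read_feature_table()`: a tibble ready for [fs_data()].
#' @export
read_feature_table <- function(path,
                               split_fractions = c(0.602, 0.298, 0.100),
                               seed = 1) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!"label" %in% names(data)) {
    stop("input table must contain a 'label' column", call. = FALSE)
  }
  if (!"split" %in% names(data)) {
    data$split <- make_splits(nrow(data), fractions = split_fractions,
                              labels = as.integer(data$label), seed = seed)
  }
  data
}

#' @rdname read_feature_table
#' @param experiment An `fs_experiment`.
#' @param dir Output directory (created if missing).
#' @return `write_results()`: invisibly, the paths written.
#' @export
write_results <- function(experiment, dir) {
  stopifnot(inherits(experiment, "fs_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  results_path <- file.path(dir, "results.csv")
  readr::write_csv(experiment$summary, results_path)
  runs_path <- file.path(dir, "runs.csv")
  readr::write_csv(experiment$runs, runs_path)
  meta_path <- file.path(dir, "metadata.json")
  meta <- list(
    algorithm = experiment$algorithm,
    seeds = experiment$seeds,
    config = unclass(experiment$config),
    selected = lapply(experiment$fits, function(f) f$selected)
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results_path, runs_path, meta_path))
}
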
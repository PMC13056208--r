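# Seeded synthetic-data generators.  They emulate (i) the learned
# 100-dimensional representation entering the wrapper feature selector --
# two-class Gaussian features with a controllable number of informative
# dimensions and effect size -- and (ii) multi-subject ROI time series whose
# between-class difference lives purely in the correlation structure, so the
# connectivity stack has a recoverable ground truth.  Ground-truth metadata
# (informative indices, coupled ROI pair) always travels with the data.

#' Generate a two-class Gaussian feature dataset
#'
#' Class-0 features are standard normal; class-1 *informative* features are
#' shifted by `delta` (in units of the within-class standard deviation),
#' noise features stay standard normal. Labels are assigned by
#' `class_balance` and rows carry a stratified train/validation/test split
#' (see [make_splits()]).
#'
#' @param n Number of samples.
#' @param d Number of features.
#' @param d_inf Number of informative features (`0 <= d_inf <= d`); these
#'   are features `1..d_inf`.
#' @param delta Class mean shift on informative features, in within-class
#'   sigma units.
#' @param class_balance Proportion of positive (label 1) samples, default
#'   0.5.
#' @param split_fractions Train/validation/test fractions (defaults from a
#'   623/308/104 three-way split of 1,035 subjects).
#' @param seed Integer seed.
#' @return A tibble with feature columns `f1..fd`, `label` (0/1) and
#'   `split`; attributes `informative` (ground-truth indices) and `spec`.
#' @examples
#' d <- gen_feature_dataset(n = 60, d = 10, d_inf = 3, delta = 1, seed = 1)
#' dplyr::count(d, label, split)
#' @export
gen_feature_dataset <- function(n, d, d_inf, delta,
                                class_balance = 0.5,
                                split_fractions = c(0.602, 0.298, 0.100),
                                seed = 1) {
  stopifnot(n >= 4, d >= 1, d_inf >= 0, d_inf <= d, delta >= 0,
            class_balance > 0, class_balance < 1)
  rng <- new_rng(seed)
  n_pos <- round(n * class_balance)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  x <- matrix(rng_norm(rng, n * d), nrow = n, ncol = d)
  if (d_inf > 0 && n_pos > 0) {
    x[labels == 1, seq_len(d_inf)] <- x[labels == 1, seq_len(d_inf)] + delta
  }
  split <- make_splits(n, fractions = split_fractions, labels = labels,
                       seed = as.integer((seed + 104729) %% 2147483647))
  colnames(x) <- paste0("f", seq_len(d))
  out <- tibble::as_tibble(x)
  out$label <- labels
  out$split <- split
  attr(out, "informative") <- seq_len(d_inf)
  attr(out, "spec") <- list(n = n, d = d, d_inf = d_inf, delta = delta,
                            class_balance = class_balance, seed = seed)
  out
}

#' Generate multi-subject ROI time series
#'
#' Per subject a `t_len x r` Gaussian series. A designated ROI pair (1, 2)
#' carries the class difference: its correlation is `base_cor` for class 0
#' and `base_cor + coupling_delta` for class 1 (class 1 higher); all other
#' ROIs are independent. Used to verify that the Pearson-connectivity stack
#' can separate the classes.
#'
#' @param n_subjects Number of subjects.
#' @param r Number of ROIs (`>= 2`).
#' @param t_len Time points per subject (`>= 3`).
#' @param coupling_delta Between-class correlation difference on the
#'   designated pair.
#' @param base_cor Class-0 correlation of the pair, default 0.1.
#' @param class_balance Proportion of positive subjects.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `label`, and `series` (list
#'   column of `t_len x r` matrices); attribute `coupled_pair = c(1, 2)`.
#' @export
gen_roi_timeseries <- function(n_subjects, r, t_len, coupling_delta,
                               base_cor = 0.1, class_balance = 0.5,
                               seed = 1) {
  stopifnot(r >= 2, t_len >= 3, coupling_delta >= 0,
            base_cor + coupling_delta < 1)
  rng <- new_rng(seed)
  n_pos <- round(n_subjects * class_balance)
  labels <- c(rep(1L, n_pos), rep(0L, n_subjects - n_pos))
  series <- lapply(seq_len(n_subjects), function(i) {
    rho <- base_cor + if (labels[i] == 1) coupling_delta else 0
    z <- matrix(rng_norm(rng, t_len * r), nrow = t_len, ncol = r)
    # correlate ROI 2 with ROI 1 at the target level
    z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    colnames(z) <- paste0("roi", seq_len(r))
    z
  })
  out <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
    label = labels,
    series = series
  )
  attr(out, "coupled_pair") <- c(1L, 2L)
  out
}

#' Stratified train/validation/test assignment
#'
#' Splits `n` rows into `train`, `validation` and `test` by the given
#' fractions using largest-remainder rounding; when labels are supplied the
#' partition is stratified by label (largest remainder within each class).
#' The default fractions reproduce a 623/308/104 partition of 1,035
#' subjects. Errors when any split ends up without both classes.
#'
#' @param n Number of rows.
#' @param fractions Length-3 numeric summing to 1 (tolerance 1e-9).
#' @param labels Optional binary vector for stratification.
#' @param seed Integer seed.
#' @return Character vector of length `n` with values
#'   `"train"`, `"validation"`, `"test"`.
#' @examples
#' table(make_splits(1035, labels = rep(0:1, c(530, 505)), seed = 1))
#' @export
make_splits <- function(n, fractions = c(0.602, 0.298, 0.100),
                        labels = NULL, seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) <= 1e-9)
  rng <- new_rng(seed)
  split_counts <- function(m) {
    raw <- fractions * m
    base <- floor(raw)
    left <- m - sum(base)
    if (left > 0) {
      extra <- order(-(raw - base))[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  assign_group <- function(m) {
    counts <- split_counts(m)
    rep(c("train", "validation", "test"), counts)[order(rng_unif(rng, m))]
  }
  if (is.null(labels)) {
    out <- assign_group(n)
  } else {
    stopifnot(length(labels) == n)
    out <- character(n)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      out[idx] <- assign_group(length(idx))
    }
  }
  if (!is.null(labels)) {
    tab <- table(out, labels)
    if (any(tab == 0) || nrow(tab) < 3) {
      stop("a split was left without both classes; use more samples or ",
           "different fractions", call. = FALSE)
    }
  }
  out
}
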
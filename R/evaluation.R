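# Classification metrics and run aggregation.  The positive class (label 1)
# is the clinical class of interest (ASD in the motivating application).

#' Confusion counts
#'
#' @param y_true,y_pred Binary vectors (0/1) of equal length; 1 is the
#'   positive class.
#' @return A tibble with `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tibble::tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and the F-score (harmonic mean of precision and
#' sensitivity). Ratios with a zero denominator are reported as 0 with a
#' warning rather than aborting an experiment sweep.
#'
#' @param counts A one-row tibble/list with `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `precision`,
#'   `fscore`.
#' @export
compute_metrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  stopifnot(total > 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_div(counts$tp, counts$tp + counts$fn, "sensitivity")
  prec <- safe_div(counts$tp, counts$tp + counts$fp, "precision")
  fsc <- if (prec + sens == 0) {
    0
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble::tibble(
    accuracy = (counts$tp + counts$tn) / total,
    sensitivity = sens,
    precision = prec,
    fscore = fsc
  )
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with score ties counted 1/2 (the
#' Mann-Whitney estimator, computed from mid-ranks). Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive); here typically the
#'   positive-neighbour fraction of a KNN vote.
#' @param y_true Binary labels, both classes present.
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Aggregate metric values across runs
#'
#' Mean, standard deviation with the population (1/n) convention, best and
#' worst. For benefit metrics best = max and worst = min; for quantities
#' where smaller is better (selected feature counts) set
#' `higher_is_better = FALSE` to swap them.
#'
#' @param values Non-empty numeric vector.
#' @param higher_is_better Logical, default `TRUE`.
#' @return A one-row tibble with `mean`, `std`, `best`, `worst`, `n_runs`.
#' @examples
#' aggregate_runs(c(0.70, 0.72))
#' @export
aggregate_runs <- function(values, higher_is_better = TRUE) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  tibble::tibble(
    mean = m,
    std = s,
    best = if (higher_is_better) max(values) else min(values),
    worst = if (higher_is_better) min(values) else max(values),
    n_runs = length(values)
  )
}
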
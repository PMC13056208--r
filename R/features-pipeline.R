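# End-to-end feature stack: ROI time series -> Pearson connectivity vectors
# -> Fisher-score filter -> SSDAE pre-training -> MLP fine-tuning -> learned
# features ready for the wrapper selector.

#' Connectivity vectors for a set of subjects
#'
#' Computes the Pearson functional-connectivity matrix of every subject's
#' ROI time series and flattens its strict upper triangle, yielding one
#' `R(R-1)/2`-dimensional row per subject.
#'
#' @param timeseries A tibble as produced by [gen_roi_timeseries()]:
#'   columns `subject_id`, `label`, and a `series` list column of
#'   `T x R` matrices.
#' @return A tibble with columns `fc1..fcM`, `label` and `subject_id`.
#' @export
connectivity_features <- function(timeseries) {
  stopifnot(all(c("subject_id", "label", "series") %in% names(timeseries)))
  vecs <- purrr::map(timeseries$series, ~ flatten_upper(pearson_fc(.x)))
  x <- do.call(rbind, vecs)
  colnames(x) <- paste0("fc", seq_len(ncol(x)))
  out <- tibble::as_tibble(x)
  out$label <- timeseries$label
  out$subject_id <- timeseries$subject_id
  out
}

#' Learn a compact representation with the SSDAE + MLP stack
#'
#' The full feature-extraction stage: rank features by Fisher score on the
#' training split, keep the top fraction (15% by default), standardize using
#' training statistics, pre-train the two-layer SSDAE, fine-tune the MLP on
#' the training labels, and export the last-hidden-layer activations for
#' every sample.
#'
#' @param data Tibble with numeric feature columns, `label`, and optionally
#'   `split` (when absent a stratified split is drawn with `seed`); other
#'   non-feature columns (`subject_id`) are carried through.
#' @param fraction Fraction of features retained by the Fisher filter.
#' @param ssdae [ssdae_config()]; sizes must suit the filtered dimension.
#' @param mlp [mlp_config()].
#' @param seed Integer seed (networks and, if needed, the split).
#' @return A tibble of learned features `lf1..lfH` plus `label`, `split`
#'   (and `subject_id` if present); attributes `kept` (filtered feature
#'   names) and `model` (the fitted `mlp_model`).
#' @export
learn_features <- function(data, fraction = 0.15,
                           ssdae = ssdae_config(), mlp = mlp_config(),
                           seed = 1) {
  stopifnot("label" %in% names(data))
  if (!"split" %in% names(data)) {
    data$split <- make_splits(nrow(data), labels = as.integer(data$label),
                              seed = seed)
  }
  carry <- intersect(c("label", "split", "subject_id"), names(data))
  feat_cols <- setdiff(names(data), carry)
  x <- as.matrix(data[feat_cols])
  y <- as.integer(data$label)
  train <- data$split == "train"

  scores <- fisher_score(x[train, , drop = FALSE], y[train])
  kept <- filter_top_fraction(scores, fraction)
  xk <- x[, kept, drop = FALSE]
  mu <- colMeans(xk[train, , drop = FALSE])
  sd_tr <- apply(xk[train, , drop = FALSE], 2, stats::sd)
  sd_tr[sd_tr == 0] <- 1
  xs <- sweep(sweep(xk, 2, mu), 2, sd_tr, `/`)

  rng <- new_rng(seed)
  stack <- pretrain_ssdae(xs[train, , drop = FALSE], ssdae, rng)
  model <- finetune_mlp(xs[train, , drop = FALSE], y[train], stack, mlp, rng)
  lf <- extract_learned_features(model, xs)
  colnames(lf) <- paste0("lf", seq_len(ncol(lf)))

  out <- tibble::as_tibble(lf)
  for (col in carry) out[[col]] <- data[[col]]
  attr(out, "kept") <- feat_cols[kept]
  attr(out, "model") <- model
  out
}
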
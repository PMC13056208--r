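# Functional-connectivity features: Pearson correlation between ROI time
# series, strict-upper-triangle vectorization, and the Fisher-criterion
# filter that keeps the most class-discriminative fraction.

#' Pearson functional connectivity matrix
#'
#' Correlates every pair of ROI time series. Zero-variance ROIs produce 0
#' correlations (with a warning) instead of `NA`; the diagonal is always 1.
#'
#' @param ts A `T x R` matrix or data frame: rows = time points, columns =
#'   ROIs. At least 3 time points.
#' @return An `R x R` symmetric correlation matrix with unit diagonal.
#' @examples
#' ts <- matrix(rnorm(60), ncol = 3)
#' pearson_fc(ts)
#' @export
pearson_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) {
    stop("at least 3 time points are required", call. = FALSE)
  }
  fc <- suppressWarnings(stats::cor(ts))
  if (anyNA(fc)) {
    warning("zero-variance ROI(s); their correlations are reported as 0",
            call. = FALSE)
    fc[is.na(fc)] <- 0
  }
  diag(fc) <- 1
  fc
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Row-major traversal of the strict upper triangle (diagonal excluded):
#' entries `(1,2), (1,3), ..., (1,R), (2,3), ...`, giving `R(R-1)/2`
#' features (19,900 for a 200-ROI atlas; 6,670 for 116 ROIs).
#'
#' @param fc Square symmetric matrix.
#' @return Numeric vector of length `R(R-1)/2`.
#' @export
flatten_upper <- function(fc) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) {
    stop("connectivity matrix must be square", call. = FALSE)
  }
  # t(fc) indexed by lower.tri walks the upper triangle in row-major order
  tfc <- t(fc)
  tfc[lower.tri(tfc)]
}

#' Fisher score for two-class feature ranking
#'
#' Standard two-class Fisher criterion: per feature `j`,
#' `[(m1_j - m_j)^2 + (m0_j - m_j)^2] / (v1_j + v0_j)` with class means
#' `m1, m0`, overall mean `m`, and class sample variances `v1, v0`. A zero
#' denominator yields score 0. Translation-invariant.
#'
#' @param features `n x d` matrix or data frame of feature values.
#' @param labels Binary vector of length `n`, both classes present.
#' @return Numeric vector of `d` scores.
#' @export
fisher_score <- function(features, labels) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- labels == 1
  m <- colMeans(x)
  m1 <- colMeans(x[pos, , drop = FALSE])
  m0 <- colMeans(x[!pos, , drop = FALSE])
  v1 <- apply(x[pos, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!pos, , drop = FALSE], 2, stats::var)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- v1 + v0
  score <- ifelse(den == 0, 0, num / den)
  unname(score)
}

#' Keep the top-scoring fraction of features
#'
#' Returns the indices of the `floor(fraction * d)` highest-scoring features
#' (floor convention: 6,670 features at 15% retain exactly 1,000), with
#' score ties broken by the lower index. Indices are returned sorted
#' ascending.
#'
#' @param scores Numeric score vector.
#' @param fraction Fraction in `(0, 1]`, default 0.15.
#' @return Integer index vector.
#' @export
filter_top_fraction <- function(scores, fraction = 0.15) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- floor(fraction * length(scores))
  if (k < 1) {
    stop("fraction retains no features", call. = FALSE)
  }
  ord <- order(-scores) # stable: ties keep lower index first
  sort(ord[seq_len(k)])
}
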
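#' Define a bounded continuous search space
#'
#' The optimizers search a box-constrained `D`-dimensional real domain.
#' Bounds are recycled to length `d`.
#'
#' @param d Integer number of dimensions (`>= 1`).
#' @param lower,upper Per-dimension bounds; `lower[j] < upper[j]` for all `j`.
#' @return An object of class `search_space` with elements `d`, `lower`,
#'   `upper`.
#' @examples
#' search_space(3, lower = 0, upper = 1)
#' @export
search_space <- function(d, lower = 0, upper = 1) {
  d <- as.integer(d)
  stopifnot(d >= 1)
  lower <- rep_len(as.double(lower), d)
  upper <- rep_len(as.double(upper), d)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(list(d = d, lower = lower, upper = upper),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> d =", x$d, "\n")
  cat("  lower:", utils::head(x$lower, 6), if (x$d > 6) "...", "\n")
  cat("  upper:", utils::head(x$upper, 6), if (x$d > 6) "...", "\n")
  invisible(x)
}

#' Project a position onto the box
#'
#' Out-of-bounds coordinates are clamped to the nearest bound; in-bounds
#' inputs are returned unchanged. Idempotent.
#'
#' @param position Numeric vector of length `space$d` (or matrix with that
#'   many columns).
#' @param space A [search_space()].
#' @return Clamped object of the same shape.
#' @export
clip_to_bounds <- function(position, space) {
  if (is.matrix(position)) {
    stopifnot(ncol(position) == space$d)
    out <- pmin(pmax(position, rep(space$lower, each = nrow(position))),
                rep(space$upper, each = nrow(position)))
    return(out)
  }
  stopifnot(length(position) == space$d)
  pmin(pmax(position, space$lower), space$upper)
}

#' Initialize a population of candidate solutions
#'
#' Positions are drawn uniformly inside the box,
#' `X[i, j] = (UB[j] - LB[j]) * u + LB[j]`, one independent uniform draw per
#' element (matrix filled column by column). Fitness is unset until
#' [evaluate_population()] is called; at least two solutions are required so
#' the second-best position is defined.
#'
#' @param space A [search_space()].
#' @param n_pop Number of solutions (`>= 2`).
#' @param rng A [new_rng()] stream (a [fixed_rng()] stub is accepted).
#' @return A `population` list with `x` (`n_pop x d` matrix), `fit`, `xb`,
#'   `fitb`, `xs`.
#' @export
init_population <- function(space, n_pop, rng) {
  n_pop <- as.integer(n_pop)
  if (n_pop < 2) {
    stop("n_pop must be at least 2 (second-best position undefined otherwise)",
         call. = FALSE)
  }
  u <- matrix(rng_unif(rng, n_pop * space$d), nrow = n_pop, ncol = space$d)
  x <- sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
  structure(
    list(x = x, fit = rep(NA_real_, n_pop),
         xb = NULL, fitb = Inf, xs = NULL),
    class = "population"
  )
}

#' Evaluate a population and update the running best
#'
#' Applies the objective to every row, then updates the best-so-far solution
#' only when a strictly smaller fitness is found (elitism). The second-best
#' position `xs` is the row with the second-smallest *current* fitness; all
#' ties are broken by the lowest row index.
#'
#' @param pop A `population`.
#' @param objective Function mapping a length-`d` numeric vector to a finite
#'   scalar (minimization).
#' @return The updated `population`.
#' @export
evaluate_population <- function(pop, objective) {
  fit <- vapply(seq_len(nrow(pop$x)), function(i) objective(pop$x[i, ]),
                numeric(1))
  bad <- which(!is.finite(fit))
  if (length(bad)) {
    stop("objective returned a non-finite fitness for solution ", bad[1],
         call. = FALSE)
  }
  pop$fit <- fit
  ord <- order(fit)            # stable: ties keep original row order
  if (fit[ord[1]] < pop$fitb) {
    pop$fitb <- fit[ord[1]]
    pop$xb <- pop$x[ord[1], ]
  }
  pop$xs <- pop$x[ord[2], ]
  pop
}

#' Benchmark sphere objective
#'
#' `f(x) = sum(x^2)`, global minimum 0 at the origin. Used in convergence
#' sanity checks.
#'
#' @param x Numeric vector.
#' @return Scalar fitness.
#' @export
sphere <- function(x) sum(x^2)
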
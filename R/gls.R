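# Guided Learning Strategy (GLS).
#
# Past populations accumulate in an experience buffer; once the experience
# counter exceeds its cap, the per-dimension dispersion of the stored
# positions decides whether the whole population is pulled into a
# heavy-tailed local search around the best solution (high dispersion) or
# restarted uniformly across the box (low dispersion).  Replacement is
# greedy per row, so guidance never worsens any solution.

#' GLS parameters
#'
#' @param cmax Experience upper limit; `NULL` (default) means `10 * n_pop`,
#'   resolved at run time.
#' @param alpha Dispersion threshold separating the exploitation
#'   (`V0 > alpha`) and exploration branches of the guidance move. Default 1.
#' @return A list of class `gls_params`.
#' @export
gls_params <- function(cmax = NULL, alpha = 1) {
  stopifnot(is.null(cmax) || cmax >= 1, alpha > 0)
  structure(list(cmax = cmax, alpha = alpha), class = "gls_params")
}

#' Experience buffer
#'
#' `new_gls_buffer()` creates an empty buffer; [gls_record()] appends the
#' current population positions and advances the experience counter by the
#' number of solutions stored.
#'
#' @return A list with `st` (list of position matrices) and `c` (counter).
#' @export
new_gls_buffer <- function() {
  list(st = list(), c = 0L)
}

#' @rdname new_gls_buffer
#' @param buffer A buffer from `new_gls_buffer()`.
#' @param x Population position matrix (`n_pop x d`).
#' @export
gls_record <- function(buffer, x) {
  buffer$st[[length(buffer$st) + 1L]] <- x
  buffer$c <- buffer$c + nrow(x)
  buffer
}

#' Dispersion feedback value
#'
#' `V0` is the mean over dimensions of the population standard deviation
#' (1/n convention) of all stored positions in that dimension, scaled by the
#' per-dimension normalizer `B_j = 200 / (UB_j - LB_j)`; the normalizer keeps
#' `V0` invariant to the width of the search box. `V0 = 0` exactly when all
#' stored records coincide per dimension.
#'
#' @param buffer Experience buffer (must be non-empty).
#' @param space A [search_space()] (the original box).
#' @return Scalar `V0 >= 0`.
#' @export
gls_v0 <- function(buffer, space) {
  if (length(buffer$st) == 0) {
    stop("experience buffer is empty", call. = FALSE)
  }
  stacked <- do.call(rbind, buffer$st)
  mu <- colMeans(stacked)
  sd_pop <- sqrt(colMeans(sweep(stacked, 2, mu)^2))
  b <- 200 / (space$upper - space$lower)
  mean(sd_pop * b)
}

#' Guidance move
#'
#' Generates a guided population `Xn`. When `V0 > alpha` (high dispersion)
#' every element is a heavy-tailed step around the best solution,
#' `xb_j + tan(R pi) (UB_j - LB_j) / V0`; otherwise a uniform restart
#' `LB_j + R (UB_j - LB_j)`. `R` is drawn per element (an `n_pop x d` matrix
#' filled column by column) and redrawn while `|R - 0.5| < 1e-9` to avoid
#' the tangent singularity.
#'
#' @param xb Best-so-far position.
#' @param v0 Dispersion value from [gls_v0()].
#' @param space A [search_space()].
#' @param params [gls_params()].
#' @param n_pop Number of rows to generate.
#' @param rng Draw stream.
#' @return An `n_pop x d` matrix (not yet clipped).
#' @export
gls_guidance <- function(xb, v0, space, params, n_pop, rng) {
  stopifnot(v0 >= 0)
  r <- matrix(rng_unif(rng, n_pop * space$d), nrow = n_pop)
  bad <- abs(r - 0.5) < 1e-9
  while (any(bad)) {
    r[bad] <- rng_unif(rng, sum(bad))
    bad <- abs(r - 0.5) < 1e-9
  }
  width <- space$upper - space$lower
  if (v0 > params$alpha) {
    sweep(tan(r * pi), 2, width / v0, `*`) +
      matrix(xb, nrow = n_pop, ncol = space$d, byrow = TRUE)
  } else {
    sweep(sweep(r, 2, width, `*`), 2, space$lower, `+`)
  }
}

#' Apply GLS to a population
#'
#' No-op unless the experience counter exceeds `cmax`. When triggered:
#' compute `V0`, generate the guided population, clip it to the box,
#' evaluate it, keep per row whichever of the current and guided solutions
#' is better (greedy), update the elitist best, and clear the buffer
#' (`C = 0`).
#'
#' @param pop A `population` (evaluated).
#' @param buffer Experience buffer.
#' @param space A [search_space()].
#' @param params [gls_params()].
#' @param objective Objective function.
#' @param rng Draw stream.
#' @return List with `pop`, `buffer`, `fired` (logical), `v0` (or `NA`), and
#'   `n_evals` consumed.
#' @export
gls_apply <- function(pop, buffer, space, params, objective, rng) {
  n_pop <- nrow(pop$x)
  cmax <- if (is.null(params$cmax)) 10 * n_pop else params$cmax
  if (buffer$c <= cmax) {
    return(list(pop = pop, buffer = buffer, fired = FALSE, v0 = NA_real_,
                n_evals = 0L))
  }
  v0 <- gls_v0(buffer, space)
  xn <- clip_to_bounds(
    gls_guidance(pop$xb, v0, space, params, n_pop, rng), space
  )
  fit_n <- vapply(seq_len(n_pop), function(i) objective(xn[i, ]), numeric(1))
  if (any(!is.finite(fit_n))) {
    stop("objective returned a non-finite fitness during guidance",
         call. = FALSE)
  }
  take <- fit_n < pop$fit
  pop$x[take, ] <- xn[take, , drop = FALSE]
  pop$fit[take] <- fit_n[take]
  ord <- order(pop$fit)
  if (pop$fit[ord[1]] < pop$fitb) {
    pop$fitb <- pop$fit[ord[1]]
    pop$xb <- pop$x[ord[1], ]
  }
  pop$xs <- pop$x[ord[2], ]
  list(pop = pop, buffer = new_gls_buffer(), fired = TRUE, v0 = v0,
       n_evals = n_pop)
}
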
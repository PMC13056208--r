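# Exponential-Trigonometric Optimization (ETO).
#
# The two shape parameters d1 and d2 are exact negatives of each other, so
# their ratio is -1 wherever it is defined and 0/0 at cosine zeros; the ratio
# is therefore implemented as the guarded constant -1 everywhere (continuity,
# and faithful to the printed formulas).  Draw-order contract used by the
# oracle tests: each operator consumes, per solution, its branch draw(s)
# first and then one uniform vector of length d for the element-wise factor.

.d_ratio <- -1

#' ETO parameters
#'
#' @param a,b Adjustment coefficients of the constrained-exploration (CE)
#'   schedule; defaults 4.6 and 1.55.
#' @return A list of class `eto_params`.
#' @export
eto_params <- function(a = 4.6, b = 1.55) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "eto_params")
}

#' ETO control quantities
#'
#' `eto_d_pair()` returns the symmetric shape pair
#' `d1 = 0.1 cos(0.5 tmax (1 - t/tmax)) exp(-0.01 t)` and `d2 = -d1`.
#' `eto_cm()` draws the changeover value
#' `CM = 0.01 u (t/tmax)^tan(d1/d2)` (exponent `tan(-1)` under the ratio
#' guard); `CM > 1` selects the phase-1 update, `CM < 1` the phase-2 update.
#' `eto_transition()` gives the exploration/exploitation switch iteration
#' `T = floor(1.2 + tmax/2.25)`.
#'
#' @param t Current iteration (`eto_cm()` requires `t >= 1`).
#' @param tmax Iteration budget.
#' @param rng Draw stream.
#' @return `eto_d_pair()`: named numeric `c(d1, d2)`; the others: a scalar.
#' @export
eto_d_pair <- function(t, tmax) {
  stopifnot(t >= 0, t <= tmax)
  d1 <- 0.1 * cos(0.5 * tmax * (1 - t / tmax)) * exp(-0.01 * t)
  c(d1 = d1, d2 = -d1)
}

#' @rdname eto_d_pair
#' @export
eto_cm <- function(t, tmax, rng) {
  stopifnot(t >= 1, t <= tmax)
  0.01 * rng_unif(rng, 1) * (t / tmax)^tan(.d_ratio)
}

#' @rdname eto_d_pair
#' @export
eto_transition <- function(tmax) {
  stopifnot(tmax >= 1)
  as.integer(floor(1.2 + tmax / 2.25))
}

#' Constrained-exploration (CE) schedule
#'
#' The first adaptation event is `CE_1 = floor(1 + tmax/b)`; each later one is
#' `CE_(i+1) = floor(2 - 2 t (tmax - CE_i a)) + CE_i`, as printed. The
#' recurrence grows explosively in practice, so typically at most one event
#' fires within the budget; values beyond `tmax` mean no further events.
#'
#' @param tmax Iteration budget.
#' @param params [eto_params()].
#' @param ce_i Current event iteration.
#' @param t Iteration at which the event fired.
#' @return Integer iteration index.
#' @export
eto_ce_first <- function(tmax, params = eto_params()) {
  as.integer(floor(1 + tmax / params$b))
}

#' @rdname eto_ce_first
#' @export
eto_ce_next <- function(ce_i, t, tmax, params = eto_params()) {
  floor(2 - 2 * t * (tmax - ce_i * params$a)) + ce_i
}

#' CE bound adaptation
#'
#' At a CE event the sampling bounds become, per dimension `j`,
#' `UB_j = r1 (1 - t/tmax) (r2 |xb_j - xs_j| + xb_j)` and `LB_j` the negated
#' expression with a fresh `(r1, r2)` pair. Draw order: the `(r1, r2)` pair
#' for the upper bound, then the pair for the lower bound (4 draws per
#' event). When any dimension would end with `LB > UB` the event is reported
#' as not applicable (`ok = FALSE`) and callers keep the previous bounds; the
#' original box is always used for final feasibility clipping.
#'
#' @param xb,xs Best and second-best positions.
#' @param t,tmax Iteration and budget.
#' @param rng Draw stream.
#' @return List with `upper`, `lower`, `ok`.
#' @export
eto_ce_bounds <- function(xb, xs, t, tmax, rng) {
  r <- rng_unif(rng, 4)
  fac <- 1 - t / tmax
  upper <- r[1] * fac * (r[2] * abs(xb - xs) + xb)
  lower <- -(r[3] * fac * (r[4] * abs(xb - xs) + xb))
  list(upper = upper, lower = lower, ok = all(lower <= upper))
}

#' ETO weighting coefficients
#'
#' One coefficient is drawn per iteration and shared by all solutions:
#' `alpha1 = 3u (t/tmax - 0.85) exp(d1/d2 - 1)` (one draw),
#' `alpha2 = u1 exp(tanh(1.5 (-t/tmax - 0.75) - u2))` (two draws),
#' `alpha3 = 3u (t/tmax - 0.85) exp(|d1/d2| - 1.3)` (one draw), and the
#' draw-free constant `c = exp(tan(d1/d2))`, all with the ratio guard
#' `d1/d2 = -1`. `alpha1` and `alpha3` vanish at `t/tmax = 0.85` and share
#' the sign of `t/tmax - 0.85`.
#'
#' @param t,tmax Iteration and budget.
#' @param rng Draw stream.
#' @return Scalar coefficient.
#' @export
eto_alpha1 <- function(t, tmax, rng) {
  3 * rng_unif(rng, 1) * (t / tmax - 0.85) * exp(.d_ratio - 1)
}

#' @rdname eto_alpha1
#' @export
eto_alpha2 <- function(t, tmax, rng) {
  u <- rng_unif(rng, 2)
  u[1] * exp(tanh(1.5 * (-t / tmax - 0.75) - u[2]))
}

#' @rdname eto_alpha1
#' @export
eto_alpha3 <- function(t, tmax, rng) {
  3 * rng_unif(rng, 1) * (t / tmax - 0.85) * exp(abs(.d_ratio) - 1.3)
}

#' @rdname eto_alpha1
#' @export
eto_c_coef <- function() exp(tan(.d_ratio))

#' ETO position updates
#'
#' The four phase operators for one solution. Per solution,
#' `eto_explore1()` consumes the branch draw `q1` then `d` element draws and
#' returns `xb +/- u alpha1 |xb - xi|` (`+` when `q1 <= 0.5`);
#' `eto_explore2()` consumes `q2` then `d` draws for
#' `xi +/- 3 u alpha2 |xb - xi|`; `eto_exploit1()` consumes `q3`, `q4` then
#' `d` draws for `xb +/- q4 alpha3 u |xb - xi|`; `eto_exploit2()` consumes
#' `d` draws for `xi + c u alpha2 |xb - xi|`.
#'
#' @param xi Current position.
#' @param xb Best-so-far position.
#' @param alpha1,alpha2,alpha3 Iteration coefficients (see [eto_alpha1()]).
#' @param c_coef The diversity constant [eto_c_coef()].
#' @param rng Draw stream.
#' @return Updated position vector (not yet clipped).
#' @export
eto_explore1 <- function(xi, xb, alpha1, rng) {
  q1 <- rng_unif(rng, 1)
  u <- rng_unif(rng, length(xi))
  s <- if (q1 <= 0.5) 1 else -1
  xb + s * u * alpha1 * abs(xb - xi)
}

#' @rdname eto_explore1
#' @export
eto_explore2 <- function(xi, xb, alpha2, rng) {
  q2 <- rng_unif(rng, 1)
  u <- rng_unif(rng, length(xi))
  s <- if (q2 <= 0.5) 1 else -1
  xi + s * 3 * u * alpha2 * abs(xb - xi)
}

#' @rdname eto_explore1
#' @export
eto_exploit1 <- function(xi, xb, alpha3, rng) {
  q <- rng_unif(rng, 2) # q3 branch, q4 magnitude
  u <- rng_unif(rng, length(xi))
  s <- if (q[1] <= 0.5) 1 else -1
  xb + s * q[2] * alpha3 * u * abs(xb - xi)
}

#' @rdname eto_explore1
#' @export
eto_exploit2 <- function(xi, xb, alpha2, c_coef, rng) {
  u <- rng_unif(rng, length(xi))
  xi + c_coef * u * alpha2 * abs(xb - xi)
}

#' Run the ETO optimizer
#'
#' Full dual-phase exploration/exploitation loop: per iteration the shape
#' pair and changeover value are computed, the CE schedule may adapt the
#' sampling bounds, and every solution is moved by the phase operator chosen
#' by `t <= T` (exploration vs exploitation) and `CM > 1` (phase 1 vs 2).
#' Positions are clipped to the original box and evaluated with elitist
#' best-keeping.
#'
#' @param objective Function: numeric vector of length `space$d` -> scalar
#'   cost (minimized).
#' @param space A [search_space()].
#' @param n_pop Population size (`>= 2`).
#' @param tmax Iteration budget.
#' @param params [eto_params()].
#' @param rng A [new_rng()] stream (or a seed accepted via `seed`).
#' @param seed Convenience integer seed used when `rng` is missing.
#' @param ce Logical: run the CE bound-adaptation schedule (default `TRUE`).
#' @return An `optim_result`: list with `best`, `best_fitness`, `trace`
#'   (tibble of per-iteration best fitness), `n_evals`, `algorithm`.
#' @examples
#' res <- eto_run(sphere, search_space(2, -5, 5), n_pop = 10, tmax = 50,
#'                seed = 1)
#' res$best_fitness
#' @export
eto_run <- function(objective, space, n_pop = 20, tmax = 100,
                    params = eto_params(), rng = NULL, seed = 1, ce = TRUE) {
  if (is.null(rng)) rng <- new_rng(seed)
  pop <- init_population(space, n_pop, rng)
  pop <- evaluate_population(pop, objective)
  t_switch <- eto_transition(tmax)
  ce_next <- if (ce) eto_ce_first(tmax, params) else NA_integer_
  lb_cur <- space$lower
  ub_cur <- space$upper
  trace <- numeric(tmax)

  for (t in seq_len(tmax)) {
    cm <- eto_cm(t, tmax, rng)
    if (ce && !is.na(ce_next) && t == ce_next) {
      bounds <- eto_ce_bounds(pop$xb, pop$xs, t, tmax, rng)
      if (bounds$ok) {
        ub_cur <- bounds$upper
        lb_cur <- bounds$lower
      }
      nxt <- eto_ce_next(ce_next, t, tmax, params)
      ce_next <- if (nxt > tmax || nxt <= t) NA_integer_ else as.integer(nxt)
    }
    explore <- t <= t_switch
    phase1 <- cm > 1
    newx <- pop$x
    if (explore && phase1) {
      a1 <- eto_alpha1(t, tmax, rng)
      for (i in seq_len(n_pop)) {
        newx[i, ] <- eto_explore1(pop$x[i, ], pop$xb, a1, rng)
      }
    } else if (explore) {
      a2 <- eto_alpha2(t, tmax, rng)
      for (i in seq_len(n_pop)) {
        newx[i, ] <- eto_explore2(pop$x[i, ], pop$xb, a2, rng)
      }
    } else if (phase1) {
      a3 <- eto_alpha3(t, tmax, rng)
      for (i in seq_len(n_pop)) {
        newx[i, ] <- eto_exploit1(pop$x[i, ], pop$xb, a3, rng)
      }
    } else {
      a2 <- eto_alpha2(t, tmax, rng)
      cc <- eto_c_coef()
      for (i in seq_len(n_pop)) {
        newx[i, ] <- eto_exploit2(pop$x[i, ], pop$xb, a2, cc, rng)
      }
    }
    pop$x <- clip_to_bounds(newx, space)
    pop <- evaluate_population(pop, objective)
    trace[t] <- pop$fitb
  }

  new_optim_result(
    algorithm = "eto", best = pop$xb, best_fitness = pop$fitb,
    trace = trace, n_evals = n_pop * (tmax + 1), space = space,
    population = pop$x, fit = pop$fit
  )
}
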
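# Arithmetic Optimization Algorithm (AOA).
#
# Exploration moves use the Division / Multiplication operators, exploitation
# the Subtraction / Addition operators, scheduled by the accelerated function
# MOA and the math-optimizer probability MOP.  The exploration scale is
# implemented mu-free, "((UB - LB) + LB)", as printed; setting
# `mu_in_exploration = TRUE` restores the canonical AOA scale
# "((UB - LB) mu + LB)" for users who want the original algorithm.

#' AOA parameters
#'
#' @param min,max Bounds of the accelerated function MOA (defaults 0.2, 0.9;
#'   unstated in the source experiments, common AOA settings).
#' @param alpha Sensitivity exponent of MOP, fixed at 5.
#' @param mu Search-control parameter, 0.5.
#' @param epsilon Small positive guard preventing division by zero in the
#'   Division operator (1e-12).
#' @param mu_in_exploration Logical; include `mu` in the exploration scale
#'   (canonical AOA) instead of the printed mu-free form. Default `FALSE`.
#' @return A list of class `aoa_params`.
#' @export
aoa_params <- function(min = 0.2, max = 0.9, alpha = 5, mu = 0.5,
                       epsilon = 1e-12, mu_in_exploration = FALSE) {
  stopifnot(min >= 0, min < max, max <= 1, alpha > 0, mu > 0, mu <= 1,
            epsilon > 0)
  structure(list(min = min, max = max, alpha = alpha, mu = mu,
                 epsilon = epsilon, mu_in_exploration = mu_in_exploration),
            class = "aoa_params")
}

#' AOA schedules
#'
#' `aoa_moa()` is the linear accelerated function
#' `MOA(t) = Min + t (Max - Min)/tmax`; `aoa_mop()` the math-optimizer
#' probability `MOP(t) = 1 - t^(1/alpha)/tmax^(1/alpha)`, decreasing from 1
#' at `t = 0` to 0 at `t = tmax`.
#'
#' @param t,tmax Iteration and budget (`0 <= t <= tmax`).
#' @param params [aoa_params()].
#' @return Scalar value.
#' @export
aoa_moa <- function(t, tmax, params = aoa_params()) {
  stopifnot(t >= 0, t <= tmax)
  params$min + t * (params$max - params$min) / tmax
}

#' @rdname aoa_moa
#' @export
aoa_mop <- function(t, tmax, params = aoa_params()) {
  stopifnot(t >= 0, t <= tmax)
  1 - t^(1 / params$alpha) / tmax^(1 / params$alpha)
}

#' AOA position updates for one solution
#'
#' `aoa_explore()` applies, per dimension, the Division operator
#' `xb_j / (MOP + eps) * scale_j` when `r2 < 0.5` and the Multiplication
#' operator `xb_j * MOP * scale_j` otherwise, with
#' `scale_j = (UB_j - LB_j) + LB_j` (mu-free as printed).
#' `aoa_exploit()` applies Subtraction `xb_j - MOP * step_j` when `r3 < 0.5`
#' and Addition `xb_j + MOP * step_j` otherwise, with
#' `step_j = (UB_j - LB_j) mu + LB_j`. One `r2`/`r3` draw per dimension.
#'
#' @param xb Best-so-far position.
#' @param mop Current MOP value.
#' @param lower,upper Current per-dimension bounds.
#' @param params [aoa_params()].
#' @param rng Draw stream.
#' @return Updated position vector (not yet clipped).
#' @export
aoa_explore <- function(xb, mop, lower, upper, params = aoa_params(), rng) {
  r2 <- rng_unif(rng, length(xb))
  scale <- if (params$mu_in_exploration) {
    (upper - lower) * params$mu + lower
  } else {
    (upper - lower) + lower
  }
  ifelse(r2 < 0.5,
         xb / (mop + params$epsilon) * scale,
         xb * mop * scale)
}

#' @rdname aoa_explore
#' @export
aoa_exploit <- function(xb, mop, lower, upper, params = aoa_params(), rng) {
  r3 <- rng_unif(rng, length(xb))
  step <- mop * ((upper - lower) * params$mu + lower)
  ifelse(r3 < 0.5, xb - step, xb + step)
}

#' Run the AOA optimizer
#'
#' Per iteration and solution one draw `r1` selects the phase
#' (`r1 > MOA(t)`: exploration, else exploitation); the per-dimension
#' operator choice then uses `r2` (Division/Multiplication) or `r3`
#' (Subtraction/Addition). Positions are clipped to the box and evaluated
#' with elitist best-keeping.
#'
#' @inheritParams eto_run
#' @param params [aoa_params()].
#' @return An `optim_result` (see [eto_run()]).
#' @examples
#' res <- aoa_run(sphere, search_space(2, -5, 5), n_pop = 10, tmax = 50,
#'                seed = 1)
#' res$best_fitness
#' @export
aoa_run <- function(objective, space, n_pop = 20, tmax = 100,
                    params = aoa_params(), rng = NULL, seed = 1) {
  if (is.null(rng)) rng <- new_rng(seed)
  pop <- init_population(space, n_pop, rng)
  pop <- evaluate_population(pop, objective)
  trace <- numeric(tmax)

  for (t in seq_len(tmax)) {
    moa <- aoa_moa(t, tmax, params)
    mop <- aoa_mop(t, tmax, params)
    newx <- pop$x
    for (i in seq_len(n_pop)) {
      r1 <- rng_unif(rng, 1)
      newx[i, ] <- if (r1 > moa) {
        aoa_explore(pop$xb, mop, space$lower, space$upper, params, rng)
      } else {
        aoa_exploit(pop$xb, mop, space$lower, space$upper, params, rng)
      }
    }
    pop$x <- clip_to_bounds(newx, space)
    pop <- evaluate_population(pop, objective)
    trace[t] <- pop$fitb
  }

  new_optim_result(
    algorithm = "aoa", best = pop$xb, best_fitness = pop$fitb,
    trace = trace, n_evals = n_pop * (tmax + 1), space = space,
    population = pop$x, fit = pop$fit
  )
}
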
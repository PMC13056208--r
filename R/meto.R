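# METO: ETO control flow with fitness-proportional injection of AOA
# operators and periodic GLS.
#
# Per-iteration draw order (the contract the oracle tests replay):
#   1. changeover value CM (1 draw);
#   2. CE bound adaptation if t equals the next scheduled event (4 draws);
#   3. selection threshold rp (1 draw; skipped when the hybrid branch is
#      disabled or rp is overridden);
#   4. the phase coefficient shared by all solutions: alpha1 or alpha3
#      (1 draw) when CM > 1, alpha2 (2 draws) otherwise;
#   5. per solution, in row order: the AOA operator (d draws) when
#      P_i < rp, else the ETO operator (branch draws then d element draws);
#   6. at GLS iterations with the counter over its cap, the guidance matrix
#      (n_pop * d draws, column-major, plus singularity redraws).

#' METO parameters
#'
#' @param eto [eto_params()].
#' @param aoa [aoa_params()].
#' @param gls [gls_params()].
#' @param gls_period Guidance is attempted every `gls_period` iterations
#'   (default 10, the `rem(t, 10) == 0` gate).
#' @return A list of class `meto_params`.
#' @export
meto_params <- function(eto = eto_params(), aoa = aoa_params(),
                        gls = gls_params(), gls_period = 10) {
  stopifnot(gls_period >= 1)
  structure(list(eto = eto, aoa = aoa, gls = gls,
                 gls_period = as.integer(gls_period)),
            class = "meto_params")
}

#' Fitness-proportional selection for operator injection
#'
#' `selection_probabilities()` normalizes raw fitness values to shares
#' `P_i = Fit_i / sum(Fit)`; with minimization costs, better solutions get
#' *smaller* shares and are likelier to take the AOA branch (`P_i < rp`), as
#' printed. An all-zero fitness vector degenerates to the uniform `1/N`.
#' `selection_threshold()` draws `rp = min(P) + u (max(P) - min(P))` (one
#' draw per iteration).
#'
#' @param fit Numeric fitness vector (finite).
#' @param p Probability shares.
#' @param rng Draw stream.
#' @return Numeric vector of shares / scalar threshold.
#' @export
selection_probabilities <- function(fit) {
  stopifnot(all(is.finite(fit)))
  s <- sum(fit)
  if (s == 0) {
    return(rep(1 / length(fit), length(fit)))
  }
  fit / s
}

#' @rdname selection_probabilities
#' @export
selection_threshold <- function(p, rng) {
  stopifnot(length(p) >= 1)
  min(p) + rng_unif(rng, 1) * (max(p) - min(p))
}

#' Run the METO hybrid optimizer
#'
#' ETO bookkeeping (shape pair, changeover value, CE schedule) drives the
#' iteration; each solution is updated either by the AOA operator for the
#' current phase (Division/Multiplication while exploring, Subtraction/
#' Addition while exploiting) when its fitness share falls below the drawn
#' threshold, or by the ETO operator with the changeover value choosing the
#' phase-1 or phase-2 variant. Every iteration is recorded in the GLS
#' experience buffer and guidance is attempted whenever
#' `t mod gls_period == 0` (subject to the experience-counter gate).
#'
#' The AOA donor operators read the current (possibly CE-adapted) sampling
#' bounds; feasibility clipping always uses the original box.
#'
#' @inheritParams eto_run
#' @param params [meto_params()].
#' @param hybrid Logical; `FALSE` disables the AOA branch entirely (no
#'   threshold draw), reducing METO to ETO control flow.
#' @param gls Logical; `FALSE` disables experience recording and guidance.
#' @param ce Logical; `FALSE` disables the CE schedule.
#' @param rp_override Numeric; when supplied, used as the selection
#'   threshold instead of drawing one (e.g. `-Inf` forces every solution
#'   onto the ETO branch, `Inf` onto the AOA branch).
#' @return An `optim_result` with additionally a `branches` tibble of
#'   per-iteration AOA/ETO row counts and GLS events.
#' @examples
#' res <- meto_run(sphere, search_space(2, -5, 5), n_pop = 10, tmax = 50,
#'                 seed = 1)
#' res$best_fitness
#' @export
meto_run <- function(objective, space, n_pop = 20, tmax = 100,
                     params = meto_params(), rng = NULL, seed = 1,
                     hybrid = TRUE, gls = TRUE, ce = TRUE,
                     rp_override = NULL) {
  if (is.null(rng)) rng <- new_rng(seed)
  pop <- init_population(space, n_pop, rng)
  pop <- evaluate_population(pop, objective)
  t_switch <- eto_transition(tmax)
  ce_next <- if (ce) eto_ce_first(tmax, params$eto) else NA_integer_
  lb_cur <- space$lower
  ub_cur <- space$upper
  buffer <- new_gls_buffer()
  trace <- numeric(tmax)
  n_aoa <- integer(tmax)
  gls_fired <- logical(tmax)
  n_evals <- n_pop

  for (t in seq_len(tmax)) {
    cm <- eto_cm(t, tmax, rng)
    if (ce && !is.na(ce_next) && t == ce_next) {
      bounds <- eto_ce_bounds(pop$xb, pop$xs, t, tmax, rng)
      if (bounds$ok) {
        ub_cur <- bounds$upper
        lb_cur <- bounds$lower
      }
      nxt <- eto_ce_next(ce_next, t, tmax, params$eto)
      ce_next <- if (nxt > tmax || nxt <= t) NA_integer_ else as.integer(nxt)
    }

    use_aoa <- rep(FALSE, n_pop)
    if (hybrid) {
      p <- selection_probabilities(pop$fit)
      rp <- if (is.null(rp_override)) {
        selection_threshold(p, rng)
      } else {
        rp_override
      }
      use_aoa <- p < rp
    }

    explore <- t <= t_switch
    phase1 <- cm > 1
    a1 <- a2 <- a3 <- NA_real_
    cc <- eto_c_coef()
    if (explore && phase1) {
      a1 <- eto_alpha1(t, tmax, rng)
    } else if (explore) {
      a2 <- eto_alpha2(t, tmax, rng)
    } else if (phase1) {
      a3 <- eto_alpha3(t, tmax, rng)
    } else {
      a2 <- eto_alpha2(t, tmax, rng)
    }
    mop <- aoa_mop(t, tmax, params$aoa)

    newx <- pop$x
    for (i in seq_len(n_pop)) {
      newx[i, ] <- if (use_aoa[i]) {
        if (explore) {
          aoa_explore(pop$xb, mop, lb_cur, ub_cur, params$aoa, rng)
        } else {
          aoa_exploit(pop$xb, mop, lb_cur, ub_cur, params$aoa, rng)
        }
      } else if (explore && phase1) {
        eto_explore1(pop$x[i, ], pop$xb, a1, rng)
      } else if (explore) {
        eto_explore2(pop$x[i, ], pop$xb, a2, rng)
      } else if (phase1) {
        eto_exploit1(pop$x[i, ], pop$xb, a3, rng)
      } else {
        eto_exploit2(pop$x[i, ], pop$xb, a2, cc, rng)
      }
    }
    pop$x <- clip_to_bounds(newx, space)
    pop <- evaluate_population(pop, objective)
    n_evals <- n_evals + n_pop

    if (gls) {
      buffer <- gls_record(buffer, pop$x)
      if (t %% params$gls_period == 0) {
        res <- gls_apply(pop, buffer, space, params$gls, objective, rng)
        pop <- res$pop
        buffer <- res$buffer
        gls_fired[t] <- res$fired
        n_evals <- n_evals + res$n_evals
      }
    }

    trace[t] <- pop$fitb
    n_aoa[t] <- sum(use_aoa)
  }

  out <- new_optim_result(
    algorithm = "meto", best = pop$xb, best_fitness = pop$fitb,
    trace = trace, n_evals = n_evals, space = space,
    population = pop$x, fit = pop$fit
  )
  out$branches <- tibble::tibble(
    iter = seq_len(tmax), n_aoa = n_aoa, n_eto = n_pop - n_aoa,
    gls_fired = gls_fired
  )
  out
}

# --- optimizer registry -----------------------------------------------------

.optimizers <- new.env(parent = emptyenv())

#' Optimizer registry
#'
#' All optimizers honour the same run contract
#' `fun(objective, space, n_pop, tmax, rng = , seed = )` and return an
#' `optim_result`, so drivers (feature selection, CLI) can swap algorithms
#' by name. `meto`, `eto` and `aoa` are pre-registered; external optimizers
#' (e.g. comparison methods) can be plugged in with `register_optimizer()`.
#'
#' @param name Algorithm name (case-insensitive).
#' @param fun Run function honouring the contract.
#' @return `get_optimizer()` returns the run function;
#'   `list_optimizers()` the registered names.
#' @export
register_optimizer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(tolower(name), fun, envir = .optimizers)
  invisible(name)
}

#' @rdname register_optimizer
#' @export
get_optimizer <- function(name) {
  key <- tolower(name)
  if (!exists(key, envir = .optimizers, inherits = FALSE)) {
    stop("unknown optimizer '", name, "'; registered: ",
         paste(list_optimizers(), collapse = ", "), call. = FALSE)
  }
  get(key, envir = .optimizers, inherits = FALSE)
}

#' @rdname register_optimizer
#' @export
list_optimizers <- function() sort(ls(envir = .optimizers))
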
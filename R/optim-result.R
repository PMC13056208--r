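#' Optimizer result container
#'
#' Internal constructor shared by [eto_run()], [aoa_run()] and [meto_run()].
#' The per-iteration best fitness is stored as a tibble so results pipe
#' straight into dplyr/ggplot2.
#'
#' @param algorithm Name of the algorithm.
#' @param best Best position found.
#' @param best_fitness Its fitness.
#' @param trace Numeric vector of per-iteration best fitness.
#' @param n_evals Total objective evaluations.
#' @param space The [search_space()] searched.
#' @param population Final position matrix.
#' @param fit Final fitness vector.
#' @return An object of class `optim_result`.
#' @keywords internal
new_optim_result <- function(algorithm, best, best_fitness, trace, n_evals,
                             space, population = NULL, fit = NULL) {
  structure(
    list(
      algorithm = algorithm,
      best = best,
      best_fitness = best_fitness,
      trace = tibble::tibble(iter = seq_along(trace), best_fitness = trace),
      n_evals = n_evals,
      space = space,
      population = population,
      fit = fit
    ),
    class = "optim_result"
  )
}

#' @export
print.optim_result <- function(x, ...) {
  cat("<optim_result:", x$algorithm, "> d =", x$space$d,
      " evals =", x$n_evals, "\n")
  cat("  best fitness:", format(x$best_fitness, digits = 8), "\n")
  invisible(x)
}

#' Tidy an optimizer result
#'
#' `tidy()` returns the per-iteration convergence trace; `glance()` a
#' one-row summary.
#'
#' @param x An `optim_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy optim_result
#' @export
tidy.optim_result <- function(x, ...) {
  dplyr::mutate(x$trace, algorithm = x$algorithm, .before = 1)
}

#' @rdname tidy.optim_result
#' @method glance optim_result
#' @export
glance.optim_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    d = x$space$d,
    n_evals = x$n_evals,
    best_fitness = x$best_fitness
  )
}

#' Plot a convergence trace
#'
#' Best-so-far fitness against iteration, on a log10 fitness scale when all
#' values are positive.
#'
#' @param object An `optim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot optim_result
#' @export
autoplot.optim_result <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$iter,
                                         y = .data$best_fitness)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = paste("Convergence:", object$algorithm)) +
    ggplot2::theme_minimal()
  if (all(dat$best_fitness > 0)) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
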
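# Independent straight-line oracles written in base R only.  They replay the
# same injected uniform-draw sequence as the implementation under its
# documented draw-order contract, but share no code with the package.

# Loop-free-in-spirit re-implementation of the full METO iteration: explicit
# arithmetic for every rule (initialization, changeover value, CE schedule,
# selection threshold, the four ETO operators, the AOA donor operators, and
# the GLS guidance with greedy merge).
straightline_meto <- function(values, n, d, lb, ub, tmax, objective,
                              gls_period = 10, cmax = 10 * n,
                              alpha_gls = 1) {
  pos <- 0
  nxt <- function(k) {
    out <- values[pos + seq_len(k)]
    pos <<- pos + k
    stopifnot(!anyNA(out))
    out
  }
  lb <- rep(lb, length.out = d)
  ub <- rep(ub, length.out = d)

  u <- matrix(nxt(n * d), nrow = n, ncol = d)
  x <- u * matrix(ub - lb, n, d, byrow = TRUE) +
    matrix(lb, n, d, byrow = TRUE)
  fit <- apply(x, 1, objective)
  ord <- order(fit)
  xb <- x[ord[1], ]
  fitb <- fit[ord[1]]
  xs <- x[ord[2], ]

  t_switch <- floor(1.2 + tmax / 2.25)
  ce_next <- floor(1 + tmax / 1.55)
  lb_cur <- lb
  ub_cur <- ub
  st <- NULL
  cc_exp <- 0
  trace <- numeric(tmax)

  for (t in seq_len(tmax)) {
    cm <- 0.01 * nxt(1) * (t / tmax)^tan(-1)
    if (!is.na(ce_next) && t == ce_next) {
      r <- nxt(4)
      fac <- 1 - t / tmax
      ubc <- r[1] * fac * (r[2] * abs(xb - xs) + xb)
      lbc <- -(r[3] * fac * (r[4] * abs(xb - xs) + xb))
      if (all(lbc <= ubc)) {
        ub_cur <- ubc
        lb_cur <- lbc
      }
      nxt_ce <- floor(2 - 2 * t * (tmax - ce_next * 4.6)) + ce_next
      ce_next <- if (nxt_ce > tmax || nxt_ce <= t) NA else nxt_ce
    }

    p <- fit / sum(fit)
    rp <- min(p) + nxt(1) * (max(p) - min(p))

    explore <- t <= t_switch
    phase1 <- cm > 1
    if (explore && phase1) {
      alpha1 <- 3 * nxt(1) * (t / tmax - 0.85) * exp(-1 - 1)
    } else if (explore) {
      uu <- nxt(2)
      alpha2 <- uu[1] * exp(tanh(1.5 * (-t / tmax - 0.75) - uu[2]))
    } else if (phase1) {
      alpha3 <- 3 * nxt(1) * (t / tmax - 0.85) * exp(abs(-1) - 1.3)
    } else {
      uu <- nxt(2)
      alpha2 <- uu[1] * exp(tanh(1.5 * (-t / tmax - 0.75) - uu[2]))
    }
    c_coef <- exp(tan(-1))
    mop <- 1 - t^(1 / 5) / tmax^(1 / 5)

    newx <- x
    for (i in seq_len(n)) {
      if (p[i] < rp) {
        if (explore) {
          r2 <- nxt(d)
          scale <- (ub_cur - lb_cur) + lb_cur
          newx[i, ] <- ifelse(r2 < 0.5,
                              xb / (mop + 1e-12) * scale,
                              xb * mop * scale)
        } else {
          r3 <- nxt(d)
          step <- mop * ((ub_cur - lb_cur) * 0.5 + lb_cur)
          newx[i, ] <- ifelse(r3 < 0.5, xb - step, xb + step)
        }
      } else if (explore && phase1) {
        q1 <- nxt(1)
        uu <- nxt(d)
        s <- if (q1 <= 0.5) 1 else -1
        newx[i, ] <- xb + s * uu * alpha1 * abs(xb - x[i, ])
      } else if (explore) {
        q2 <- nxt(1)
        uu <- nxt(d)
        s <- if (q2 <= 0.5) 1 else -1
        newx[i, ] <- x[i, ] + s * 3 * uu * alpha2 * abs(xb - x[i, ])
      } else if (phase1) {
        q34 <- nxt(2)
        uu <- nxt(d)
        s <- if (q34[1] <= 0.5) 1 else -1
        newx[i, ] <- xb + s * q34[2] * alpha3 * uu * abs(xb - x[i, ])
      } else {
        uu <- nxt(d)
        newx[i, ] <- x[i, ] + c_coef * uu * alpha2 * abs(xb - x[i, ])
      }
    }
    x <- pmin(pmax(newx, matrix(lb, n, d, byrow = TRUE)),
              matrix(ub, n, d, byrow = TRUE))
    fit <- apply(x, 1, objective)
    ord <- order(fit)
    if (fit[ord[1]] < fitb) {
      fitb <- fit[ord[1]]
      xb <- x[ord[1], ]
    }
    xs <- x[ord[2], ]

    st <- rbind(st, x)
    cc_exp <- cc_exp + n
    if (t %% gls_period == 0 && cc_exp > cmax) {
      mu <- colMeans(st)
      sd_pop <- sqrt(colMeans(sweep(st, 2, mu)^2))
      v0 <- mean(sd_pop * 200 / (ub - lb))
      r <- matrix(nxt(n * d), nrow = n)
      bad <- abs(r - 0.5) < 1e-9
      while (any(bad)) {
        r[bad] <- nxt(sum(bad))
        bad <- abs(r - 0.5) < 1e-9
      }
      xn <- if (v0 > alpha_gls) {
        matrix(xb, n, d, byrow = TRUE) +
          tan(r * pi) * matrix((ub - lb) / v0, n, d, byrow = TRUE)
      } else {
        matrix(lb, n, d, byrow = TRUE) +
          r * matrix(ub - lb, n, d, byrow = TRUE)
      }
      xn <- pmin(pmax(xn, matrix(lb, n, d, byrow = TRUE)),
                 matrix(ub, n, d, byrow = TRUE))
      fit_n <- apply(xn, 1, objective)
      take <- fit_n < fit
      x[take, ] <- xn[take, , drop = FALSE]
      fit[take] <- fit_n[take]
      ord <- order(fit)
      if (fit[ord[1]] < fitb) {
        fitb <- fit[ord[1]]
        xb <- x[ord[1], ]
      }
      xs <- x[ord[2], ]
      st <- NULL
      cc_exp <- 0
    }
    trace[t] <- fitb
  }
  list(trace = trace, x = x, fit = fit, xb = xb, fitb = fitb, drawn = pos)
}

# All-pairs AUC with the 1/2 tie convention.
bruteforce_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# Small deterministic dataset builder for wrapper tests: two Gaussian blobs
# separated by `delta` on the first `d_inf` features.
make_blob_data <- function(n = 120, d = 10, d_inf = 3, delta = 3, seed = 1) {
  gen_feature_dataset(n = n, d = d, d_inf = d_inf, delta = delta,
                      seed = seed)
}
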
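# Stacked sparse denoising autoencoder (SSDAE) pre-training and MLP
# fine-tuning, written with plain matrix algebra so the networks are small,
# dependency-free and exactly reproducible from a draw stream.
#
# The architecture mirrors the connectivity pipeline: two greedily trained
# denoising autoencoders (encoding sizes 1000 then 600 at full scale) whose
# encoder weights initialize the first two layers of a supervised MLP ending
# in a 100-unit layer; the activations of that last hidden layer are the
# learned features handed to the wrapper feature selector.  All sizes are
# configuration-driven so tests and examples run scaled-down stacks.

sigmoid <- function(z) stats::plogis(z)

glorot_init <- function(n_in, n_out, rng) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix((2 * rng_unif(rng, n_in * n_out) - 1) * lim, nrow = n_in)
}

#' SSDAE configuration
#'
#' Defaults are the full-scale settings of the connectivity pipeline:
#' encoder sizes 1000 and 600, masking-noise fraction 0.2, sparsity target
#' 0.05 with penalty weight 1e-3, learning rate 0.001, batch size 100,
#' dropout 0.5, and 700 / 1000 training epochs for the first / second
#' autoencoder. Training uses mini-batch gradient descent.
#'
#' @param hidden Integer vector of the two (strictly decreasing) encoder
#'   sizes.
#' @param noise Masking-noise fraction applied to inputs.
#' @param sparsity_target Target mean activation of encoder units.
#' @param sparsity_weight Weight of the KL sparsity penalty.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Integer vector: epochs for each autoencoder.
#' @param dropout Dropout rate on the encoding layer during training.
#' @return A list of class `ssdae_config`.
#' @export
ssdae_config <- function(hidden = c(1000, 600), noise = 0.2,
                         sparsity_target = 0.05, sparsity_weight = 1e-3,
                         lr = 0.001, batch_size = 100,
                         epochs = c(700, 1000), dropout = 0.5) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), hidden[2] < hidden[1],
            noise >= 0, noise < 1, sparsity_target > 0, sparsity_target < 1,
            sparsity_weight >= 0, lr > 0, batch_size >= 1,
            length(epochs) == 2, all(epochs >= 1),
            dropout >= 0, dropout < 1)
  structure(list(hidden = as.integer(hidden), noise = noise,
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout),
            class = "ssdae_config")
}

#' MLP configuration
#'
#' Full-scale defaults: hidden sizes 1000, 600, 100 (the first two must
#' match the SSDAE encoders, whose weights initialize them), learning rate
#' 0.0005, batch size 10 (stochastic gradient descent), dropout 0.3. The
#' number of supervised epochs is not pinned by the pipeline description;
#' the default of 100 is exposed here.
#'
#' @param hidden Integer vector of three hidden sizes.
#' @param lr,batch_size,dropout,epochs Training hyper-parameters.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(1000, 600, 100), lr = 0.0005,
                       batch_size = 10, dropout = 0.3, epochs = 100) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), lr > 0, batch_size >= 1,
            dropout >= 0, dropout < 1, epochs >= 1)
  structure(list(hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 epochs = as.integer(epochs)),
            class = "mlp_config")
}

# One denoising autoencoder: sigmoid encoder, linear decoder, mean-squared
# reconstruction loss plus KL sparsity penalty on the batch-mean activation.
train_dae <- function(x, k, cfg, epochs, rng) {
  n <- nrow(x)
  d <- ncol(x)
  w1 <- glorot_init(d, k, rng)
  b1 <- numeric(k)
  w2 <- glorot_init(k, d, rng)
  b2 <- numeric(d)
  rho <- cfg$sparsity_target
  keep <- 1 - cfg$dropout
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- order(rng_unif(rng, n))
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      nb <- nrow(xb)
      # masking noise: zero each input element independently
      xc <- xb
      if (cfg$noise > 0) {
        mask_in <- rng_unif(rng, nb * d) >= cfg$noise
        xc <- xb * matrix(mask_in, nb, d)
      }
      h <- sigmoid(sweep(xc %*% w1, 2, b1, `+`))
      rho_hat <- pmin(pmax(colMeans(h), 1e-6), 1 - 1e-6)
      hd <- h
      if (cfg$dropout > 0) {
        mask_h <- (rng_unif(rng, nb * k) >= cfg$dropout) / keep
        hd <- h * matrix(mask_h, nb, k)
      }
      xhat <- sweep(hd %*% w2, 2, b2, `+`)
      err <- xhat - xb
      kl <- sum(rho * log(rho / rho_hat) +
                  (1 - rho) * log((1 - rho) / (1 - rho_hat)))
      loss <- mean(err^2) + cfg$sparsity_weight * kl
      if (!is.finite(loss)) {
        stop("non-finite autoencoder loss at epoch ", ep, call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L

      d_xhat <- 2 * err / (nb * d)
      g_w2 <- crossprod(hd, d_xhat)
      g_b2 <- colSums(d_xhat)
      d_hd <- d_xhat %*% t(w2)
      d_h <- if (cfg$dropout > 0) d_hd * matrix(mask_h, nb, k) else d_hd
      d_sparse <- cfg$sparsity_weight *
        (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / nb
      d_h <- sweep(d_h, 2, d_sparse, `+`)
      d_z <- d_h * h * (1 - h)
      g_w1 <- crossprod(xc, d_z)
      g_b1 <- colSums(d_z)

      w1 <- w1 - cfg$lr * g_w1
      b1 <- b1 - cfg$lr * g_b1
      w2 <- w2 - cfg$lr * g_w2
      b2 <- b2 - cfg$lr * g_b2
    }
    loss_trace[ep] <- ep_loss / n_batches
  }
  list(w_enc = w1, b_enc = b1, w_dec = w2, b_dec = b2,
       loss_trace = loss_trace)
}

#' Greedy layer-wise SSDAE pre-training
#'
#' Trains the first denoising autoencoder on the input features, encodes
#' them, and trains the second autoencoder on the codes. Returns the two
#' encoder layers (weights and biases) used to initialize the MLP.
#'
#' @param features `n x d` numeric matrix or data frame.
#' @param config [ssdae_config()].
#' @param rng Draw stream ([new_rng()]).
#' @return An object of class `ssdae`: list with `layers` (two
#'   weight/bias pairs), `config`, and per-layer `loss_trace`s.
#' @export
pretrain_ssdae <- function(features, config = ssdae_config(), rng = NULL,
                           seed = 1) {
  if (is.null(rng)) rng <- new_rng(seed)
  x <- as.matrix(features)
  ae1 <- train_dae(x, config$hidden[1], config, config$epochs[1], rng)
  h1 <- sigmoid(sweep(x %*% ae1$w_enc, 2, ae1$b_enc, `+`))
  ae2 <- train_dae(h1, config$hidden[2], config, config$epochs[2], rng)
  structure(
    list(
      layers = list(
        list(w = ae1$w_enc, b = ae1$b_enc),
        list(w = ae2$w_enc, b = ae2$b_enc)
      ),
      loss_traces = list(ae1$loss_trace, ae2$loss_trace),
      config = config
    ),
    class = "ssdae"
  )
}

#' @rdname pretrain_ssdae
#' @param seed Convenience seed used when `rng` is missing.
#' @export
print.ssdae <- function(x, ...) {
  sizes <- vapply(x$layers, function(l) ncol(l$w), integer(1))
  cat("<ssdae>", nrow(x$layers[[1]]$w), "->",
      paste(sizes, collapse = " -> "), "\n")
  invisible(x)
}

mlp_forward <- function(weights, x, dropout = 0, rng = NULL) {
  acts <- list()
  h <- x
  n_hidden <- length(weights) - 1L
  for (l in seq_len(n_hidden)) {
    h <- sigmoid(sweep(h %*% weights[[l]]$w, 2, weights[[l]]$b, `+`))
    if (dropout > 0) {
      mask <- (rng_unif(rng, length(h)) >= dropout) / (1 - dropout)
      acts[[l]] <- list(h = h, mask = matrix(mask, nrow(h)))
      h <- h * acts[[l]]$mask
    } else {
      acts[[l]] <- list(h = h, mask = NULL)
    }
  }
  out_l <- weights[[n_hidden + 1L]]
  yhat <- sigmoid(sweep(h %*% out_l$w, 2, out_l$b, `+`))[, 1]
  list(acts = acts, yhat = yhat)
}

#' Supervised MLP fine-tuning from SSDAE weights
#'
#' Builds an MLP whose first two hidden layers are initialized from the
#' pre-trained SSDAE encoders (their shapes must match `config$hidden[1:2]`),
#' adds the final hidden layer and a sigmoid output, and trains it with
#' mini-batch stochastic gradient descent on the binary cross-entropy.
#'
#' @param features `n x d` matrix or data frame.
#' @param labels Binary vector of length `n`.
#' @param ssdae Result of [pretrain_ssdae()].
#' @param config [mlp_config()].
#' @param rng Draw stream.
#' @param seed Convenience seed used when `rng` is missing.
#' @return An object of class `mlp_model` with `weights`, `loss_trace`,
#'   `config`.
#' @export
finetune_mlp <- function(features, labels, ssdae, config = mlp_config(),
                         rng = NULL, seed = 1) {
  if (is.null(rng)) rng <- new_rng(seed)
  x <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  enc_sizes <- vapply(ssdae$layers, function(l) ncol(l$w), integer(1))
  if (!identical(enc_sizes, config$hidden[1:2])) {
    stop("SSDAE encoder sizes (", paste(enc_sizes, collapse = ", "),
         ") do not match the first two MLP layers (",
         paste(config$hidden[1:2], collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(ssdae$layers[[1]]$w) != ncol(x)) {
    stop("input dimension does not match the pre-trained stack",
         call. = FALSE)
  }
  weights <- list(
    list(w = ssdae$layers[[1]]$w, b = ssdae$layers[[1]]$b),
    list(w = ssdae$layers[[2]]$w, b = ssdae$layers[[2]]$b),
    list(w = glorot_init(config$hidden[2], config$hidden[3], rng),
         b = numeric(config$hidden[3])),
    list(w = glorot_init(config$hidden[3], 1L, rng), b = 0)
  )
  n <- nrow(x)
  loss_trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- order(rng_unif(rng, n))
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- nrow(xb)
      fwd <- mlp_forward(weights, xb, config$dropout, rng)
      yhat <- pmin(pmax(fwd$yhat, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(yhat) + (1 - yb) * log(1 - yhat))
      if (!is.finite(loss)) {
        stop("non-finite MLP loss at epoch ", ep, call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L

      # backprop; sigmoid output with cross-entropy gives (yhat - y)
      delta <- matrix((fwd$yhat - yb) / nb, ncol = 1)
      grads <- vector("list", length(weights))
      for (l in rev(seq_along(weights))) {
        h_prev <- if (l == 1) {
          xb
        } else {
          a <- fwd$acts[[l - 1]]
          if (is.null(a$mask)) a$h else a$h * a$mask
        }
        grads[[l]] <- list(w = crossprod(h_prev, delta), b = colSums(delta))
        if (l > 1) {
          a <- fwd$acts[[l - 1]]
          d_h <- delta %*% t(weights[[l]]$w)
          if (!is.null(a$mask)) d_h <- d_h * a$mask
          delta <- d_h * a$h * (1 - a$h)
        }
      }
      for (l in seq_along(weights)) {
        weights[[l]]$w <- weights[[l]]$w - config$lr * grads[[l]]$w
        weights[[l]]$b <- weights[[l]]$b - config$lr * grads[[l]]$b
      }
    }
    loss_trace[ep] <- ep_loss / n_batches
  }
  structure(list(weights = weights, loss_trace = loss_trace,
                 config = config),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  sizes <- c(nrow(x$weights[[1]]$w),
             vapply(x$weights, function(l) ncol(l$w), integer(1)))
  cat("<mlp_model>", paste(sizes, collapse = " -> "), "\n")
  invisible(x)
}

#' Predict from a fine-tuned MLP
#'
#' @param object An `mlp_model`.
#' @param newdata `n x d` matrix or data frame.
#' @param type `"response"` for positive-class probabilities, `"class"` for
#'   0/1 labels at threshold 0.5.
#' @param ... Unused.
#' @return Numeric (or integer) vector of length `n`.
#' @export
predict.mlp_model <- function(object, newdata,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object$weights, as.matrix(newdata))$yhat
  if (type == "class") as.integer(p > 0.5) else p
}

#' Extract learned features from the last hidden layer
#'
#' Row-wise deterministic forward pass (no noise, no dropout) returning the
#' activations of the final hidden layer (100 units at full scale), one row
#' per sample.
#'
#' @param model An `mlp_model`.
#' @param features `n x d` matrix or data frame.
#' @return `n x hidden[3]` numeric matrix.
#' @export
extract_learned_features <- function(model, features) {
  fwd <- mlp_forward(model$weights, as.matrix(features))
  fwd$acts[[length(fwd$acts)]]$h
}
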
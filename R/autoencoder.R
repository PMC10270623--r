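#' Autoencoder hyperparameter configuration
#'
#' The network is symmetric: `hidden_layers` ReLU layers of `hidden_units`
#' units on the encoder side, a linear bottleneck of `bottleneck` units (the
#' learned representation; its width is fixed at configuration time, never
#' data-dependent), and a mirrored ReLU decoder with a linear output layer.
#' Training minimizes plain mean squared reconstruction error over all
#' columns (indicator and scaled numeric alike) with minibatch Adam at a
#' fixed learning rate — no schedulers, fixed betas (0.9, 0.999) — so a seed
#' fully determines the fit.
#'
#' @param hidden_layers Hidden layers per side, excluding the bottleneck.
#' @param hidden_units Units in each hidden layer.
#' @param bottleneck Bottleneck width (>= 1, <= input width at fit time).
#' @param learning_rate Positive fixed learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param activation `"relu"` (default) or `"linear"` hidden activations;
#'   linear nets are mainly useful for capability checks (a linear AE with a
#'   full-width bottleneck can represent the identity).
#' @param seed Integer seed controlling init and batch shuffling.
#' @return An `ae_config`.
#' @export
ae_config <- function(hidden_layers = 3L, hidden_units = 16L, bottleneck = 6L,
                      learning_rate = 0.001, epochs = 200L, batch_size = 64L,
                      activation = c("relu", "linear"), seed = 1L) {
  activation <- match.arg(activation)
  if (learning_rate <= 0) ps_param_error("learning_rate must be positive")
  if (bottleneck < 1) ps_param_error("bottleneck must be >= 1")
  if (hidden_layers < 1) ps_param_error("need at least one hidden layer")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 bottleneck = as.integer(bottleneck),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 activation = activation, seed = as.integer(seed)),
            class = "ae_config")
}

ae_widths <- function(p, config) {
  enc <- rep(config$hidden_units, config$hidden_layers)
  c(p, enc, config$bottleneck, rev(enc), p)
}

ae_n_params <- function(p, config) {
  w <- ae_widths(p, config)
  sum(w[-length(w)] * w[-1L] + w[-1L])
}

ae_init <- function(p, config) {
  widths <- ae_widths(p, config)
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    # He initialization suits the ReLU hidden stack
    W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1L], 0,
                                  sqrt(2 / widths[l])),
                     widths[l], widths[l + 1L])
    b[[l]] <- rep(0, widths[l + 1L])
  }
  hid <- identical(config$activation %||% "relu", "linear")
  list(W = W, b = b, widths = widths,
       # linear at the bottleneck and at the output; ReLU elsewhere unless
       # the whole net is configured linear
       linear = c(rep(hid, config$hidden_layers), TRUE,
                  rep(hid, config$hidden_layers), TRUE))
}

ae_forward <- function(net, x) {
  acts <- vector("list", length(net$W) + 1L)
  acts[[1L]] <- x
  for (l in seq_along(net$W)) {
    z <- acts[[l]] %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    acts[[l + 1L]] <- if (net$linear[l]) z else pmax(z, 0)
  }
  acts
}

ae_mse <- function(net, x) {
  out <- ae_forward(net, x)[[length(net$W) + 1L]]
  mean((out - x)^2)
}

#' Fit an autoencoder
#'
#' Deterministic given `config$seed`. A run whose loss becomes non-finite is
#' returned as a flagged failure (`diverged = TRUE`) carrying its config
#' rather than raising, so a grid search can keep going.
#'
#' @param x_train Scaled training matrix (from the encoding step).
#' @param x_test Optional scaled test matrix with the same width; its
#'   reconstruction MSE is traced per epoch.
#' @param config An [ae_config()].
#' @return A `trained_ae`: `config`, `weights`, `train_loss` / `test_loss`
#'   traces (MSE per epoch), `diverged`.
#' @export
fit_autoencoder <- function(x_train, x_test = NULL, config = ae_config()) {
  x_train <- as.matrix(x_train)
  if (!is.null(x_test)) {
    x_test <- as.matrix(x_test)
    if (ncol(x_test) != ncol(x_train)) ps_validation_error("train/test widths differ")
  }
  p <- ncol(x_train)
  if (config$bottleneck > p) ps_param_error("bottleneck exceeds input width")
  n <- nrow(x_train)
  set.seed(config$seed)
  net <- ae_init(p, config)
  n_layers <- length(net$W)
  # Adam state (first/second moment estimates per parameter tensor)
  m_W <- v_W <- lapply(net$W, function(w) w * 0)
  m_b <- v_b <- lapply(net$b, function(b) b * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  train_loss <- test_loss <- rep(NA_real_, config$epochs)
  diverged <- FALSE

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x_train[idx, , drop = FALSE]
      acts <- ae_forward(net, xb)
      out <- acts[[n_layers + 1L]]
      delta <- 2 * (out - xb) / length(xb)   # d(MSE)/d(out)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (l in n_layers:1) {
        if (!net$linear[l]) delta <- delta * (acts[[l + 1L]] > 0)
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) delta <- tcrossprod(delta, net$W[[l]])
        m_W[[l]] <- b1 * m_W[[l]] + (1 - b1) * gW
        v_W[[l]] <- b2 * v_W[[l]] + (1 - b2) * gW^2
        m_b[[l]] <- b1 * m_b[[l]] + (1 - b1) * gb
        v_b[[l]] <- b2 * v_b[[l]] + (1 - b2) * gb^2
        net$W[[l]] <- net$W[[l]] -
          config$learning_rate * corr * m_W[[l]] / (sqrt(v_W[[l]]) + eps)
        net$b[[l]] <- net$b[[l]] -
          config$learning_rate * corr * m_b[[l]] / (sqrt(v_b[[l]]) + eps)
      }
    }
    train_loss[epoch] <- ae_mse(net, x_train)
    if (!is.null(x_test)) test_loss[epoch] <- ae_mse(net, x_test)
    if (!is.finite(train_loss[epoch]) ||
        (!is.null(x_test) && !is.finite(test_loss[epoch]))) {
      diverged <- TRUE
      break
    }
  }
  last <- if (any(!is.na(train_loss))) max(which(!is.na(train_loss))) else NA_integer_
  structure(list(config = config, weights = net,
                 train_loss = train_loss, test_loss = test_loss,
                 final_train_mse = if (is.na(last)) NA_real_ else train_loss[last],
                 final_test_mse = if (is.null(x_test) || is.na(last)) NA_real_ else
                   test_loss[last],
                 diverged = diverged),
            class = "trained_ae")
}

#' @export
print.trained_ae <- function(x, ...) {
  cat(sprintf("<trained_ae> %d x %d hidden, bottleneck %d, lr %g: train MSE %.5g%s\n",
              x$config$hidden_layers, x$config$hidden_units, x$config$bottleneck,
              x$config$learning_rate, x$final_train_mse,
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Encode data with a trained autoencoder
#'
#' Runs the encoder half only; the bottleneck activations are the learned
#' representation.
#'
#' @param ae A `trained_ae`.
#' @param x Matrix with the trained input width.
#' @return m x bottleneck coordinate matrix.
#' @export
ae_encode <- function(ae, x) {
  x <- as.matrix(x)
  net <- ae$weights
  if (ncol(x) != nrow(net$W[[1L]]))
    ps_validation_error("input width does not match the trained network")
  n_enc <- ae$config$hidden_layers + 1L   # encoder hidden stack + bottleneck
  a <- x
  for (l in seq_len(n_enc)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- if (net$linear[l]) z else pmax(z, 0)
  }
  rownames(a) <- rownames(x)
  a
}

#' Reconstruct data with a trained autoencoder
#' @param ae A `trained_ae`.
#' @param x Matrix with the trained input width.
#' @return Reconstruction of `x` (same shape).
#' @export
ae_reconstruct <- function(ae, x) {
  x <- as.matrix(x)
  ae_forward(ae$weights, x)[[length(ae$weights$W) + 1L]]
}

#' Exhaustive autoencoder grid search
#'
#' Trains every combination of layer count, unit count and learning rate at
#' a fixed bottleneck width and selects the fit with minimal *test-set*
#' reconstruction MSE (ties broken by fewer parameters, then lower learning
#' rate). The default grid is layers \{2,3,4,5\} x units \{10,12,16\} x
#' learning rates \{0.1, 0.01, 0.001, 0.0001\} — 48 combinations.
#'
#' @param x_train,x_test Scaled matrices of equal width.
#' @param layers,units,learning_rates Grid axes.
#' @param bottleneck Fixed bottleneck width.
#' @param epochs,batch_size,seed Passed to every [ae_config()].
#' @return List with `best` (a `trained_ae`) and `results` (one row per
#'   combination: layers, units, learning_rate, n_params, train_mse,
#'   test_mse, diverged, selected).
#' @export
ae_grid_search <- function(x_train, x_test,
                           layers = c(2L, 3L, 4L, 5L),
                           units = c(10L, 12L, 16L),
                           learning_rates = c(0.1, 0.01, 0.001, 0.0001),
                           bottleneck = 6L, epochs = 200L, batch_size = 64L,
                           seed = 1L) {
  if (!length(layers) || !length(units) || !length(learning_rates))
    ps_param_error("grid axes must be nonempty")
  grid <- expand.grid(layers = layers, units = units, lr = learning_rates,
                      KEEP.OUT.ATTRS = FALSE)
  p <- ncol(as.matrix(x_train))
  fits <- vector("list", nrow(grid))
  res <- data.frame(layers = grid$layers, units = grid$units,
                    learning_rate = grid$lr, n_params = NA_real_,
                    train_mse = NA_real_, test_mse = NA_real_,
                    diverged = FALSE, selected = FALSE)
  for (i in seq_len(nrow(grid))) {
    cfg <- ae_config(hidden_layers = grid$layers[i], hidden_units = grid$units[i],
                     bottleneck = bottleneck, learning_rate = grid$lr[i],
                     epochs = epochs, batch_size = batch_size, seed = seed)
    fit <- fit_autoencoder(x_train, x_test, cfg)
    fits[[i]] <- fit
    res$n_params[i] <- ae_n_params(p, cfg)
    res$train_mse[i] <- fit$final_train_mse
    res$test_mse[i] <- fit$final_test_mse
    res$diverged[i] <- fit$diverged
  }
  ok <- which(!res$diverged & is.finite(res$test_mse))
  if (!length(ok)) ps_stop("all grid combinations diverged", "patsim_divergence_error")
  ord <- ok[order(res$test_mse[ok], res$n_params[ok], res$learning_rate[ok])]
  best_i <- ord[1L]
  res$selected[best_i] <- TRUE
  list(best = fits[[best_i]], results = res)
}
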
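# Minimal feed-forward network engine shared by the survival and multitask
# models: ReLU hidden layers, linear output, inverted dropout, ADAM updates.
# Sizes here are tiny (tens of inputs, <=100-unit hidden layers), so plain
# BLAS-backed matrix ops are entirely adequate.

mlp_init <- function(n_in, hidden, n_out, seed) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      # He init for ReLU layers, smaller Glorot-like scale for the output
      sc <- if (l < length(sizes) - 1L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
      list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sc),
                      fan_in, sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

# X: n x d. Returns list(out, cache) where cache holds pre/post activations
# for backprop. dropout_masks is NULL at predict time (dropout disabled).
mlp_forward <- function(layers, X, dropout_masks = NULL) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, `+`)
    if (l < L) {
      A <- Z * (Z > 0)
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
        A <- A * dropout_masks[[l]]
      }
      acts[[l + 1L]] <- A
    } else {
      acts[[l + 1L]] <- Z
    }
  }
  list(out = acts[[L + 1L]], acts = acts)
}

# grad_out: n x n_out gradient of the loss wrt the network output.
mlp_backward <- function(layers, cache, grad_out, dropout_masks = NULL) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- grad_out
  for (l in rev(seq_len(L))) {
    A_prev <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      A <- cache$acts[[l]] # post-ReLU (and post-dropout) activation of layer l-1
      delta <- delta * (A > 0)
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l - 1L]])) {
        # inverted-dropout scaling must flow through the gradient as well
        delta <- delta * dropout_masks[[l - 1L]]
      }
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    # decoupled (AdamW-style) weight decay; biases are not decayed
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps) -
      lr * weight_decay * layers[[l]]$W
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# Generic minibatch training loop. loss_fn(out, idx) -> list(loss, grad) where
# grad is wrt the network output rows of the minibatch; idx are row indices of
# X in the current batch. epoch_loss_fn(layers) -> scalar full-data loss in
# eval mode (no dropout). All randomness (shuffling, dropout masks) is drawn
# from the stream seeded by `seed`.
mlp_train <- function(layers, X, loss_fn, epoch_loss_fn, epochs, batch_size,
                      lr, dropout_rate, seed, batch_ok = NULL,
                      weight_decay = 0) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  state <- adam_init(layers)
  log <- numeric(epochs)
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        if (!is.null(batch_ok) && !batch_ok(idx)) next
        masks <- NULL
        if (dropout_rate > 0 && length(layers) > 1L) {
          masks <- lapply(seq_len(length(layers) - 1L), function(l) {
            k <- ncol(layers[[l]]$W)
            matrix(stats::rbinom(length(idx) * k, 1L, 1 - dropout_rate) /
                     (1 - dropout_rate), length(idx), k)
          })
        }
        fw <- mlp_forward(layers, X[idx, , drop = FALSE], masks)
        lg <- loss_fn(fw$out, idx)
        if (!is.finite(lg$loss)) {
          stopf("non-finite training loss at epoch %d", ep)
        }
        grads <- mlp_backward(layers, fw, lg$grad, masks)
        t <- t + 1L
        upd <- adam_step(layers, grads, state, lr, t, weight_decay)
        layers <- upd$layers
        state <- upd$state
      }
      log[ep] <- epoch_loss_fn(layers)
      if (!is.finite(log[ep])) stopf("non-finite training loss at epoch %d", ep)
    }
  })
  list(layers = layers, training_log = log)
}
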
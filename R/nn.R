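# Minimal neural-network core: dense/conv primitives on plain matrices,
# He initialisation, Adam, and a feedforward (DNN) trainer. Everything is
# driven by R's RNG so that a single set.seed() makes runs bit-reproducible.

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

relu <- function(Z) pmax(Z, 0)

# --- Adam over a flat named list of numeric arrays ------------------------

adam_new <- function(params) {
  zeros <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  list(m = zeros, v = zeros, t = 0L)
}

# weight_decay is decoupled (AdamW): applied to weight matrices, not biases
adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = st)
}

# --- MLP (used by the DNN baseline and the CNN head machinery) ------------

mlp_init <- function(n_in, hidden) {
  params <- list()
  sizes <- c(n_in, hidden, 1L)
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- he_init(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  params
}

mlp_forward <- function(params, X, n_layers) {
  A <- vector("list", n_layers + 1L)
  A[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z <- add_bias(A[[l]] %*% params[[paste0("W", l)]], params[[paste0("b", l)]])
    A[[l + 1]] <- if (l < n_layers) relu(Z) else Z
  }
  A
}

mlp_backward <- function(params, A, dOut, n_layers) {
  grads <- list()
  dZ <- dOut
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(A[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, params[[paste0("W", l)]])
      dZ <- dA * (A[[l]] > 0)
    }
  }
  grads
}

# generic seeded minibatch loop; forward_backward(params, idx) must return
# list(loss, grads); returns list(params, history)
# restore_best: keep the weights from the epoch with the lowest validation
# loss (requires eval_val); classic early stopping without a patience cutoff
sgd_loop <- function(params, n, epochs, batch_size, lr, seed,
                     forward_backward, eval_val = NULL, weight_decay = 0,
                     restore_best = FALSE) {
  set.seed(seed)
  st <- adam_new(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fb <- forward_backward(params, idx)
      if (!is.finite(fb$loss)) {
        stop("non-finite training loss at epoch ", ep,
             " (lr too high or degenerate inputs)", call. = FALSE)
      }
      losses <- c(losses, fb$loss)
      upd <- adam_step(params, fb$grads, st, lr, weight_decay = weight_decay)
      params <- upd$params
      st <- upd$state
    }
    vl <- if (is.null(eval_val)) NA_real_ else eval_val(params)
    if (restore_best && is.finite(vl) && vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_loss = vl))
  }
  out <- list(params = params, history = history, best_epoch = NA_integer_)
  if (restore_best && !is.null(best$params)) {
    out$params <- best$params
    out$best_epoch <- best$epoch
  }
  out
}
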
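# Multi-branch 1-D convolutional yield model.
#
# Each of the six weekly weather series passes through the same stack of
# 1-D convolutions (valid padding, ReLU) and one average-pooling layer;
# branch outputs are flattened and concatenated with a two-layer
# fully-connected embedding of the seven static soil/phenology features,
# then pass through three fully-connected ReLU layers and a final linear
# unit producing the scalar yield. Branch weights are shared across the six
# variables by default ("the same model applied to each series"); a
# per-variable-weights mode is available.

#' CNN architecture configuration
#'
#' @param conv_layers list of conv layer specs, each `c(filters, kernel, stride)`
#' @param pooling average-pool window (and stride), applied after the conv stack
#' @param share_branch_weights share conv weights across the six weather
#'   variables (default TRUE); when TRUE the branch parameter count is
#'   independent of the number of weather variables
#' @param static_fc_sizes two layer widths for the static (soil + phenology) branch
#' @param head_fc_sizes exactly three layer widths before the linear output
#' @return Object of class `cnn_arch_config`.
#' @export
cnn_arch_config <- function(conv_layers = list(c(8, 3, 1), c(8, 3, 1)),
                            pooling = 2,
                            share_branch_weights = TRUE,
                            static_fc_sizes = c(16, 16),
                            head_fc_sizes = c(64, 32, 16)) {
  if (length(head_fc_sizes) != 3) {
    stop("configuration error: the head must have exactly three layers ",
         "before the scalar output", call. = FALSE)
  }
  if (length(static_fc_sizes) != 2) {
    stop("configuration error: the static branch has two layers", call. = FALSE)
  }
  conv_layers <- lapply(conv_layers, function(cl) {
    cl <- as.integer(cl)
    if (length(cl) != 3 || any(cl < 1)) {
      stop("configuration error: each conv layer is c(filters, kernel, stride)",
           call. = FALSE)
    }
    cl
  })
  structure(list(conv_layers = conv_layers, pooling = as.integer(pooling),
                 share_branch_weights = isTRUE(share_branch_weights),
                 static_fc_sizes = as.integer(static_fc_sizes),
                 head_fc_sizes = as.integer(head_fc_sizes)),
            class = "cnn_arch_config")
}

#' Training configuration for gradient-trained models
#'
#' Squared-error loss minimised with Adam; the seed drives initialisation,
#' shuffling and the optional validation split, so a fixed seed reproduces
#' the loss history exactly.
#'
#' @param epochs number of passes over the training data (>= 1)
#' @param batch_size minibatch size
#' @param lr Adam learning rate (> 0)
#' @param weight_decay decoupled L2 penalty on weight matrices (not biases);
#'   the county-level noise floor of yield panels makes unregularised nets
#'   memorise, so a small decay is on by default
#' @param val_fraction fraction of training rows held out for validation
#'   monitoring (0 disables)
#' @param val_years explicit validation years (overrides `val_fraction`)
#' @param early_stopping restore the weights of the epoch with the lowest
#'   validation loss (needs a validation set); off by default
#' @param seed RNG seed
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 64, lr = 1e-3,
                         weight_decay = 1e-3,
                         val_fraction = 0, val_years = NULL,
                         early_stopping = FALSE, seed = 1L) {
  if (epochs < 1) stop("configuration error: epochs must be >= 1", call. = FALSE)
  if (lr <= 0) stop("configuration error: lr must be > 0", call. = FALSE)
  if (weight_decay < 0) stop("configuration error: weight_decay must be >= 0",
                             call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 val_fraction = val_fraction, val_years = val_years,
                 early_stopping = isTRUE(early_stopping),
                 seed = as.integer(seed)),
            class = "train_config")
}

# conv/pool output length with valid padding
conv_out_len <- function(L, k, s) {
  if (k > L) stop("configuration error: kernel size ", k,
                  " exceeds input length ", L, call. = FALSE)
  (L - k) %/% s + 1L
}

# gather indices for tap j of a conv/pool layer: maps output rows (n, t) to
# input rows (n, (t-1)*s + j) in the (N*L) x C row layout
gather_indices <- function(N, L, L_out, s, k) {
  base <- rep((0:(N - 1)) * L, each = L_out)
  lapply(seq_len(k), function(j) base + rep((0:(L_out - 1)) * s + j, times = N))
}

cached_indices <- function(icache, N, L, L_out, s, k) {
  key <- paste(N, L, L_out, s, k, sep = "_")
  if (is.null(icache[[key]])) icache[[key]] <- gather_indices(N, L, L_out, s, k)
  icache[[key]]
}

flat_rows <- function(A, N) matrix(as.vector(t(A)), nrow = N, byrow = TRUE)
unflat_rows <- function(F_, C) matrix(as.vector(t(F_)), ncol = C, byrow = TRUE)

#' Build an (untrained) multi-branch CNN
#'
#' @param arch a [cnn_arch_config()]
#' @param n_weeks weekly series length per weather variable
#' @param n_static number of static features (7 in the default pipeline)
#' @param seed RNG seed for weight initialisation
#' @return Object of class `cnn_model` (a model handle with `$params`).
#' @export
build_cnn <- function(arch = cnn_arch_config(), n_weeks = 45, n_static = 7,
                      seed = 1L) {
  stopifnot(inherits(arch, "cnn_arch_config"))
  # trace branch shapes
  L <- n_weeks
  C <- 1L
  for (cl in arch$conv_layers) {
    L <- conv_out_len(L, cl[2], cl[3])
    C <- cl[1]
  }
  Lf <- L %/% arch$pooling
  if (Lf < 1) stop("configuration error: pooling window leaves no output",
                   call. = FALSE)
  branch_out <- Lf * C

  set.seed(seed)
  params <- list()
  groups <- if (arch$share_branch_weights) "sh" else paste0("v", 1:6)
  for (g in groups) {
    Cin <- 1L
    for (l in seq_along(arch$conv_layers)) {
      cl <- arch$conv_layers[[l]]
      params[[paste0("convW", l, "_", g)]] <- he_init(cl[2] * Cin, cl[1])
      params[[paste0("convb", l, "_", g)]] <- numeric(cl[1])
      Cin <- cl[1]
    }
  }
  s <- arch$static_fc_sizes
  params$stW1 <- he_init(n_static, s[1]); params$stb1 <- numeric(s[1])
  params$stW2 <- he_init(s[1], s[2]);     params$stb2 <- numeric(s[2])
  h <- arch$head_fc_sizes
  n_concat <- 6L * branch_out + s[2]
  params$hW1 <- he_init(n_concat, h[1]); params$hb1 <- numeric(h[1])
  params$hW2 <- he_init(h[1], h[2]);     params$hb2 <- numeric(h[2])
  params$hW3 <- he_init(h[2], h[3]);     params$hb3 <- numeric(h[3])
  params$oW  <- he_init(h[3], 1L);       params$ob  <- numeric(1)

  structure(list(params = params, arch = arch,
                 n_weeks = as.integer(n_weeks), n_static = as.integer(n_static),
                 branch_out = branch_out,
                 feature_names = c(weather_column_names(n_weeks), static_columns()),
                 trained = FALSE, history = NULL, final_train_rmse = NA_real_),
            class = "cnn_model")
}

branch_group <- function(arch, v) if (arch$share_branch_weights) "sh" else paste0("v", v)

# forward one weather branch; returns flattened N x (Lf*C) plus cache
cnn_branch_forward <- function(params, g, A0, N, arch, n_weeks, icache) {
  A <- A0
  L <- n_weeks
  C <- 1L
  cache <- list()
  for (l in seq_along(arch$conv_layers)) {
    cl <- arch$conv_layers[[l]]
    L_out <- conv_out_len(L, cl[2], cl[3])
    idx <- cached_indices(icache, N, L, L_out, cl[3], cl[2])
    Acat <- do.call(cbind, lapply(idx, function(i) A[i, , drop = FALSE]))
    Z <- add_bias(Acat %*% params[[paste0("convW", l, "_", g)]],
                  params[[paste0("convb", l, "_", g)]])
    Anew <- relu(Z)
    cache[[l]] <- list(Acat = Acat, out = Anew, L_in = L, C_in = C, idx = idx)
    A <- Anew
    L <- L_out
    C <- cl[1]
  }
  w <- arch$pooling
  Lf <- L %/% w
  pidx <- cached_indices(icache, N, L, Lf, w, w)
  P <- Reduce(`+`, lapply(pidx, function(i) A[i, , drop = FALSE])) / w
  cache$pool <- list(idx = pidx, L_in = L, C = C, Lf = Lf)
  list(flat = flat_rows(P, N), cache = cache)
}

cnn_branch_backward <- function(params, g, cache, dFlat, N, arch, grads) {
  pool <- cache$pool
  dP <- unflat_rows(dFlat, pool$C)
  dA <- matrix(0, N * pool$L_in, pool$C)
  for (i in pool$idx) dA[i, ] <- dP / arch$pooling
  for (l in rev(seq_along(arch$conv_layers))) {
    cl <- arch$conv_layers[[l]]
    lc <- cache[[l]]
    dZ <- dA * (lc$out > 0)
    wn <- paste0("convW", l, "_", g)
    bn <- paste0("convb", l, "_", g)
    dW <- crossprod(lc$Acat, dZ)
    db <- colSums(dZ)
    grads[[wn]] <- if (is.null(grads[[wn]])) dW else grads[[wn]] + dW
    grads[[bn]] <- if (is.null(grads[[bn]])) db else grads[[bn]] + db
    if (l > 1L) {
      dAcat <- tcrossprod(dZ, params[[wn]])
      C_in <- lc$C_in
      dA <- matrix(0, N * lc$L_in, C_in)
      for (j in seq_along(lc$idx)) {
        cols <- ((j - 1) * C_in + 1):(j * C_in)
        dA[lc$idx[[j]], ] <- dA[lc$idx[[j]], ] + dAcat[, cols, drop = FALSE]
      }
    }
  }
  grads
}

# per-variable nested weight/bias lists for the compiled kernels (the same
# matrices are repeated six times when branch weights are shared)
branch_weight_lists <- function(params, arch) {
  nl <- length(arch$conv_layers)
  list(
    w = lapply(1:6, function(v) {
      g <- branch_group(arch, v)
      lapply(seq_len(nl), function(l) params[[paste0("convW", l, "_", g)]])
    }),
    b = lapply(1:6, function(v) {
      g <- branch_group(arch, v)
      lapply(seq_len(nl), function(l) params[[paste0("convb", l, "_", g)]])
    }),
    kernel = vapply(arch$conv_layers, `[`, integer(1), 2),
    stride = vapply(arch$conv_layers, `[`, integer(1), 3))
}

# static branch + concatenation + 3-layer head + linear output
head_forward <- function(params, Fw, S, keep_cache = FALSE) {
  H1 <- relu(add_bias(S %*% params$stW1, params$stb1))
  H2 <- relu(add_bias(H1 %*% params$stW2, params$stb2))
  Cc <- cbind(Fw, H2)
  A1 <- relu(add_bias(Cc %*% params$hW1, params$hb1))
  A2 <- relu(add_bias(A1 %*% params$hW2, params$hb2))
  A3 <- relu(add_bias(A2 %*% params$hW3, params$hb3))
  out <- add_bias(A3 %*% params$oW, params$ob)
  res <- list(pred = as.numeric(out))
  if (keep_cache) {
    res$cache <- list(S = S, H1 = H1, H2 = H2, Cc = Cc,
                      A1 = A1, A2 = A2, A3 = A3)
  }
  res
}

# returns head/static grads plus the gradient flowing into the branch
# concatenation (dFw)
head_backward <- function(params, cache, dPred, n_branch_cols) {
  grads <- list()
  dZ <- matrix(dPred, ncol = 1)
  grads$oW <- crossprod(cache$A3, dZ); grads$ob <- colSums(dZ)
  dA3 <- tcrossprod(dZ, params$oW) * (cache$A3 > 0)
  grads$hW3 <- crossprod(cache$A2, dA3); grads$hb3 <- colSums(dA3)
  dA2 <- tcrossprod(dA3, params$hW3) * (cache$A2 > 0)
  grads$hW2 <- crossprod(cache$A1, dA2); grads$hb2 <- colSums(dA2)
  dA1 <- tcrossprod(dA2, params$hW2) * (cache$A1 > 0)
  grads$hW1 <- crossprod(cache$Cc, dA1); grads$hb1 <- colSums(dA1)
  dCc <- tcrossprod(dA1, params$hW1)
  dH2 <- dCc[, (n_branch_cols + 1):ncol(dCc), drop = FALSE] * (cache$H2 > 0)
  grads$stW2 <- crossprod(cache$H1, dH2); grads$stb2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, params$stW2) * (cache$H1 > 0)
  grads$stW1 <- crossprod(cache$S, dH1); grads$stb1 <- colSums(dH1)
  list(grads = grads, dFw = dCc[, seq_len(n_branch_cols), drop = FALSE])
}

cnn_forward <- function(params, Wx, S, model, icache, keep_cache = FALSE) {
  arch <- model$arch
  N <- nrow(Wx)
  L <- model$n_weeks
  caches <- NULL
  if (keep_cache) {
    # R path: keeps the intermediate activations needed by backprop
    flats <- vector("list", 6L)
    caches <- vector("list", 6L)
    for (v in 1:6) {
      cols <- ((v - 1) * L + 1):(v * L)
      A0 <- matrix(as.vector(t(Wx[, cols, drop = FALSE])), ncol = 1)
      bf <- cnn_branch_forward(params, branch_group(arch, v), A0, N, arch, L, icache)
      flats[[v]] <- bf$flat
      caches[[v]] <- bf$cache
    }
    Fw <- do.call(cbind, flats)
  } else {
    # prediction path: compiled per-series conv branches (no large
    # intermediates); numerically identical to the R path
    bw <- branch_weight_lists(params, arch)
    Fw <- cpp_cnn_branches(Wx, L, bw$w, bw$b, bw$kernel, bw$stride,
                           arch$pooling)
  }
  hf <- head_forward(params, Fw, S, keep_cache = keep_cache)
  res <- list(pred = hf$pred)
  if (keep_cache) {
    res$cache <- c(hf$cache, list(caches = caches, N = N))
  }
  res
}

cnn_backward <- function(params, cache, dPred, model, icache) {
  arch <- model$arch
  N <- cache$N
  hb <- head_backward(params, cache, dPred, 6L * model$branch_out)
  grads <- hb$grads
  k <- model$branch_out
  for (v in 1:6) {
    dFlat <- hb$dFw[, ((v - 1) * k + 1):(v * k), drop = FALSE]
    grads <- cnn_branch_backward(params, branch_group(arch, v),
                                 cache$caches[[v]], dFlat, N, arch, grads)
  }
  # keep parameter order aligned for Adam
  grads[names(params)]
}

# compiled fast path used by the minibatch loop: branch fwd/bwd in C++,
# static branch and head through BLAS
cnn_step_fast <- function(params, Wx, S, y, model) {
  arch <- model$arch
  bw <- branch_weight_lists(params, arch)
  bf <- cpp_branch_train_fwd(Wx, model$n_weeks, bw$w, bw$b,
                             bw$kernel, bw$stride, arch$pooling)
  hf <- head_forward(params, bf$flat, S, keep_cache = TRUE)
  r <- hf$pred - y
  dPred <- 2 * r / length(r)
  hb <- head_backward(params, hf$cache, dPred, ncol(bf$flat))
  cg <- cpp_branch_train_bwd(hb$dFw, bf$acts, model$n_weeks, bw$w,
                             bw$kernel, bw$stride, arch$pooling,
                             arch$share_branch_weights)
  grads <- hb$grads
  groups <- if (arch$share_branch_weights) "sh" else paste0("v", 1:6)
  for (gi in seq_along(groups)) {
    for (l in seq_along(arch$conv_layers)) {
      grads[[paste0("convW", l, "_", groups[gi])]] <- cg[[gi]]$dW[[l]]
      grads[[paste0("convb", l, "_", groups[gi])]] <- cg[[gi]]$db[[l]]
    }
  }
  list(loss = mean(r^2), grads = grads[names(params)])
}

split_inputs <- function(model, x) {
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature schema mismatch: the table columns do not match the ",
         "model's training schema", call. = FALSE)
  }
  nw <- 6L * model$n_weeks
  list(Wx = x[, seq_len(nw), drop = FALSE],
       S = x[, (nw + 1):ncol(x), drop = FALSE])
}

#' Train the CNN
#'
#' @param model a [build_cnn()] handle
#' @param train a `feature_table` (already standardised) with yield present,
#'   or a list with elements `x` (matrix) and `y`
#' @param cfg a [train_config()]
#' @return The fitted `cnn_model`, carrying `$history` (per-epoch losses) and
#'   `$final_train_rmse` (full-pass RMSE of the returned weights).
#' @export
train_cnn <- function(model, train, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  x <- train$x
  y <- train$y
  if (is.null(y)) stop("training table has no yield", call. = FALSE)
  inp <- split_inputs(model, x)
  n <- nrow(x)

  # optional validation split (monitoring only)
  val_idx <- integer(0)
  set.seed(cfg$seed)
  if (!is.null(cfg$val_years) && inherits(train, "feature_table")) {
    val_idx <- which(train$keys$year %in% cfg$val_years)
  } else if (cfg$val_fraction > 0) {
    val_idx <- sample.int(n, max(1L, round(cfg$val_fraction * n)))
  }
  # early stopping without an explicit validation set (or when row keys are
  # unavailable to resolve val_years): fall back to a random 10% split
  if (!length(val_idx) && isTRUE(cfg$early_stopping)) {
    val_idx <- sample.int(n, max(1L, round(0.1 * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  icache <- new.env(parent = emptyenv())

  fb <- function(params, idx) {
    rows <- tr_idx[idx]
    cnn_step_fast(params, inp$Wx[rows, , drop = FALSE],
                  inp$S[rows, , drop = FALSE], y[rows], model)
  }
  eval_val <- NULL
  if (length(val_idx)) {
    eval_val <- function(params) {
      p <- cnn_forward(params, inp$Wx[val_idx, , drop = FALSE],
                       inp$S[val_idx, , drop = FALSE], model, icache)$pred
      mean((p - y[val_idx])^2)
    }
  }
  res <- sgd_loop(model$params, length(tr_idx), cfg$epochs, cfg$batch_size,
                  cfg$lr, cfg$seed, fb, eval_val,
                  weight_decay = cfg$weight_decay %||% 0,
                  restore_best = isTRUE(cfg$early_stopping))
  model$params <- res$params
  model$history <- res$history
  model$best_epoch <- res$best_epoch
  model$trained <- TRUE
  model$train_cfg <- cfg
  p <- predict(model, list(x = x))
  model$final_train_rmse <- sqrt(mean((p - y)^2))
  model
}

#' Predict yields with a (trained) CNN
#'
#' @param object a `cnn_model`
#' @param newdata a `feature_table` or list with element `x` whose columns
#'   match the training schema
#' @param chunk_size forward-pass batch size (memory bound)
#' @param ... unused
#' @return Numeric vector of predicted yields (t/ha).
#' @export
predict.cnn_model <- function(object, newdata, chunk_size = 4096L, ...) {
  x <- if (is.matrix(newdata)) newdata else newdata$x
  inp <- split_inputs(object, x)
  n <- nrow(x)
  icache <- new.env(parent = emptyenv())
  out <- numeric(n)
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    out[idx] <- cnn_forward(object$params, inp$Wx[idx, , drop = FALSE],
                            inp$S[idx, , drop = FALSE], object, icache)$pred
  }
  out
}

#' Total parameter count of a CNN handle
#' @param model a `cnn_model`
#' @return Integer number of scalar parameters.
#' @export
cnn_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
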
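# Multi-branch 1-D CNN: shape contracts, gradients, training behaviour.

tiny_arch <- cnn_arch_config(conv_layers = list(c(4, 3, 1), c(4, 3, 1)),
                             pooling = 2, static_fc_sizes = c(8, 8),
                             head_fc_sizes = c(16, 8, 8))

test_that("the model maps a batch to one scalar prediction per row", {
  m <- build_cnn(tiny_arch, n_weeks = 45, seed = 1)
  x <- matrix(rnorm(8 * 277), 8, dimnames = list(NULL, m$feature_names))
  p <- predict(m, list(x = x))
  expect_length(p, 8)
  expect_true(all(is.finite(p)))
})

test_that("all-zero weights with output bias b predict exactly b everywhere", {
  m <- build_cnn(tiny_arch, n_weeks = 20, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$ob <- 3.25
  x <- matrix(rnorm(5 * (6 * 20 + 7)), 5,
              dimnames = list(NULL, m$feature_names))
  expect_equal(predict(m, list(x = x)), rep(3.25, 5))
})

test_that("shared branch weights make the conv parameter count variable-independent", {
  shared <- build_cnn(cnn_arch_config(share_branch_weights = TRUE),
                      n_weeks = 45, seed = 1)
  pervar <- build_cnn(cnn_arch_config(share_branch_weights = FALSE),
                      n_weeks = 45, seed = 1)
  n_conv <- function(m) {
    sum(vapply(m$params[grep("^conv", names(m$params))], length, integer(1)))
  }
  expect_equal(n_conv(pervar), 6 * n_conv(shared))
  # both modes produce per-row predictions
  x <- matrix(rnorm(3 * 277), 3, dimnames = list(NULL, pervar$feature_names))
  expect_length(predict(pervar, list(x = x)), 3)
})

test_that("a kernel larger than the series length is a configuration error", {
  expect_error(build_cnn(cnn_arch_config(conv_layers = list(c(4, 12, 1))),
                         n_weeks = 10), "kernel")
  expect_error(cnn_arch_config(head_fc_sizes = c(8, 8)), "three layers")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(7)
  n_weeks <- 9
  arch <- cnn_arch_config(conv_layers = list(c(2, 3, 1), c(2, 2, 1)),
                          pooling = 2, static_fc_sizes = c(3, 3),
                          head_fc_sizes = c(4, 3, 3))
  m <- build_cnn(arch, n_weeks = n_weeks, seed = 7)
  # jitter all parameters (incl. zero-initialised biases) so no ReLU
  # pre-activation sits exactly on the non-differentiable kink
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
  x <- matrix(rnorm(4 * (6 * n_weeks + 7)), 4,
              dimnames = list(NULL, m$feature_names))
  y <- rnorm(4)
  inp <- yieldcnn:::split_inputs(m, x)
  icache <- new.env(parent = emptyenv())
  loss_at <- function(params) {
    p <- yieldcnn:::cnn_forward(params, inp$Wx, inp$S, m, icache)$pred
    mean((p - y)^2)
  }
  fw <- yieldcnn:::cnn_forward(m$params, inp$Wx, inp$S, m, icache, keep_cache = TRUE)
  grads <- yieldcnn:::cnn_backward(m$params, fw$cache,
                                   2 * (fw$pred - y) / 4, m, icache)
  h <- 1e-5
  for (nm in c("convW1_sh", "convb2_sh", "stW1", "hW2", "oW", "ob")) {
    g <- grads[[nm]]
    for (k in sample(seq_along(g), min(4, length(g)))) {
      pp <- m$params
      pp[[nm]][k] <- pp[[nm]][k] + h
      up <- loss_at(pp)
      pp[[nm]][k] <- pp[[nm]][k] - 2 * h
      dn <- loss_at(pp)
      expect_equal(g[k], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, descends, and can memorise a tiny sample", {
  sp <- small_split()
  sub <- yieldcnn:::subset_rows(sp$train, 1:32)
  cfg <- train_config(epochs = 250, batch_size = 16, lr = 3e-3,
                      weight_decay = 0, seed = 5)
  m1 <- train_cnn(build_cnn(tiny_arch, seed = 5), sub, cfg)
  # memorisation oracle: enough epochs on 32 rows drives train RMSE below
  # 0.1 x SD(yield)
  expect_lt(m1$final_train_rmse, 0.1 * sd(sub$y))
  # descent property
  expect_lte(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  # bit-identical loss history under the same seed
  m2 <- train_cnn(build_cnn(tiny_arch, seed = 5), sub, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("predictions are pure, row-independent and consistent with bookkeeping", {
  sp <- small_split()
  sub <- yieldcnn:::subset_rows(sp$train, 1:40)
  m <- train_cnn(build_cnn(tiny_arch, seed = 2), sub,
                 train_config(epochs = 5, seed = 2))
  p1 <- predict(m, sub)
  p2 <- predict(m, sub)
  expect_identical(p1, p2)
  perm <- sample(seq_along(p1))
  expect_equal(predict(m, list(x = sub$x[perm, ])), p1[perm])
  # stored final train RMSE reproduces from predictions
  expect_equal(sqrt(mean((p1 - sub$y)^2)), m$final_train_rmse,
               tolerance = 1e-6)
})

test_that("schema mismatches and validation monitoring behave as specified", {
  sp <- small_split()
  sub <- yieldcnn:::subset_rows(sp$train, 1:30)
  m <- train_cnn(build_cnn(tiny_arch, seed = 3), sub,
                 train_config(epochs = 3, seed = 3))
  bad <- sub$x
  colnames(bad)[1] <- "Gale_1"
  expect_error(predict(m, list(x = bad)), "schema mismatch")
  mv <- train_cnn(build_cnn(tiny_arch, seed = 3), sp$train,
                  train_config(epochs = 3, seed = 3, val_fraction = 0.2))
  expect_true(all(is.finite(mv$history$val_loss)))
})
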
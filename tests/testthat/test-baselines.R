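# The eight baseline learners and the CV search protocol.

test_that("euclidean distance matches the printed definition", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(2, 7), 5)  # 1-D: absolute difference
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
  # symmetry and triangle inequality on random triples
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(5); q <- rnorm(5); r <- rnorm(5)
    expect_equal(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("unknown model names fail listing the valid set", {
  expect_error(baseline_spec("adaboost"), "knn.*random_forest.*dnn")
  expect_error(make_baseline("adaboost"), "valid names")
  h <- make_baseline("knn")
  expect_s3_class(h, "model_spec")
  expect_equal(h$hyper$k, 10L)  # defaults filled in
  expect_error(baseline_spec("knn", hyper = list(neighbours = 3)),
               "unknown hyperparameter")
})

test_that("lasso in the vanishing-penalty limit approaches least squares", {
  set.seed(11)
  n <- 80
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  beta <- c(1.5, -2, 0.5, 0)
  y <- as.numeric(x %*% beta) + rnorm(n, 0, 0.05)
  fit <- fit_model(baseline_spec("lasso", hyper = list(lambda = 1e-7)), x, y)
  ls <- stats::lm.fit(cbind(1, x), y)$coefficients[-1]
  # glmnet interpolates along its path at this tiny s (warns about it)
  co <- suppressWarnings(as.numeric(stats::coef(fit$fit, s = 1e-7))[-1])
  expect_equal(co, unname(ls), tolerance = 1e-2)
})

test_that("knn degenerates to the training mean at k = n and stays convex", {
  set.seed(2)
  x <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(60, 5, 2)
  fit <- fit_model(baseline_spec("knn", hyper = list(k = 60)), x, y)
  xt <- matrix(rnorm(10 * 3), 10, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(fit, xt), rep(mean(y), 10))
  fit5 <- fit_model(baseline_spec("knn", hyper = list(k = 5)), x, y)
  p5 <- predict(fit5, xt)
  expect_true(all(p5 >= min(y) & p5 <= max(y)))
  expect_error(fit_model(baseline_spec("knn", hyper = list(k = 100)), x, y),
               "k must lie")
})

test_that("the regression tree's first split matches the exhaustive SSE oracle", {
  set.seed(4)
  x1 <- sort(runif(120, -1, 1))
  y <- as.numeric(x1 > 0) + rnorm(120, 0, 0.01)
  x <- cbind(x1 = x1, x2 = rnorm(120))
  fit <- fit_model(baseline_spec("regression_tree",
                                 hyper = list(min_node = 5, max_depth = 2)),
                   x, y)
  # brute-force SSE minimisation over all candidate splits of both features
  best <- list(sse = Inf)
  for (j in 1:2) {
    o <- order(x[, j])
    xs <- x[o, j]; ys <- y[o]
    for (i in 5:(120 - 5)) {
      if (xs[i + 1] <= xs[i]) next
      sse <- sum((ys[1:i] - mean(ys[1:i]))^2) +
        sum((ys[-(1:i)] - mean(ys[-(1:i)]))^2)
      if (sse < best$sse) best <- list(sse = sse, feature = j,
                                       thr = xs[i] + (xs[i + 1] - xs[i]) / 2)
    }
  }
  expect_equal(fit$tree$feature[1] + 1L, best$feature)
  expect_equal(fit$tree$threshold[1], best$thr)
  expect_lt(abs(best$thr), 0.12)  # the sign boundary
})

test_that("forest and boosting improve on a single tree fit and are seeded", {
  set.seed(9)
  n <- 300
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1]^2 + x[, 2] + rnorm(n, 0, 0.2)
  xt <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  yt <- xt[, 1]^2 + xt[, 2] + rnorm(200, 0, 0.2)
  stump <- fit_model(baseline_spec("regression_tree",
                                   hyper = list(max_depth = 1)), x, y)
  rf <- fit_model(baseline_spec("random_forest", seed = 3), x, y)
  gb <- fit_model(baseline_spec("xgboost", seed = 3), x, y)
  expect_lt(rmse_of(rf, xt, yt), rmse_of(stump, xt, yt))
  expect_lt(rmse_of(gb, xt, yt), rmse_of(stump, xt, yt))
  rf2 <- fit_model(baseline_spec("random_forest", seed = 3), x, y)
  expect_identical(predict(rf, xt), predict(rf2, xt))
})

test_that("linear SVR respects the epsilon tube and fits linear data", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(x %*% c(2, -1, 0.5)) + 4
  fit <- fit_model(baseline_spec("svr",
                                 hyper = list(C = 10, epsilon = 0.05,
                                              epochs = 800, lr = 0.02)), x, y)
  expect_lt(sqrt(mean((predict(fit, x) - y)^2)), 0.2)
  expect_equal(as.numeric(fit$w), c(2, -1, 0.5), tolerance = 0.1)
})

test_that("on linear data the penalised linear models match or beat the tree", {
  set.seed(21)
  n <- 1200
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.numeric(x %*% rnorm(10)) + rnorm(n, 0, 0.3)
  tr <- 1:1000; te <- 1001:1200
  r <- vapply(c("lasso", "ridge", "regression_tree"), function(nm) {
    f <- fit_model(baseline_spec(nm, seed = 1), x[tr, ], y[tr])
    rmse_of(f, x[te, ], y[te])
  }, numeric(1))
  expect_lte(r["lasso"], r["regression_tree"])
  expect_lte(r["ridge"], r["regression_tree"])
})

test_that("hyperparameter search matches exhaustive enumeration and is seeded", {
  set.seed(8)
  n <- 90
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] * 2 + rnorm(n, 0, 0.4)

  # singleton space returns that candidate
  s1 <- search_spec("grid", space = list(k = 7L), k_folds = 3, seed = 2)
  expect_equal(tune_hyperparameters("knn", s1, x, y)$best$k, 7L)

  # grid of 4 candidates: best equals the brute-force minimiser
  sp <- search_spec("grid", space = list(k = c(2L, 5L, 10L, 30L)),
                    k_folds = 3, seed = 2)
  res <- tune_hyperparameters("knn", sp, x, y)
  set.seed(2)
  folds <- sample(rep(1:3, length.out = n))
  brute <- vapply(c(2L, 5L, 10L, 30L), function(k) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      fit <- fit_model(baseline_spec("knn", hyper = list(k = k), seed = 2),
                       x[tr, , drop = FALSE], y[tr])
      sqrt(mean((predict(fit, x[!tr, , drop = FALSE]) - y[!tr])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$best$k, c(2L, 5L, 10L, 30L)[which.min(brute)])
  expect_equal(sort(res$trials$mean_cv_rmse), sort(brute), tolerance = 1e-12)

  # determinism of the full trial log
  res2 <- tune_hyperparameters("knn", sp, x, y)
  expect_identical(res$trials, res2$trials)

  expect_error(search_spec("grid", space = list()), "empty search space")
  expect_error(tune_hyperparameters("knn", sp, x[1:2, ], y[1:2]),
               "fewer rows than folds")
})
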
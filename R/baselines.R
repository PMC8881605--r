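# The eight classical comparison learners behind one fit/predict contract,
# plus the cross-validated hyperparameter search protocol.
#
# Environment note: no tree/forest/boosting/SVM packages are available, so
# the regression tree (exhaustive SSE-minimising CART, grown in C++), the
# bagged forest, the gradient-boosted ensemble filling the "xgboost" slot,
# the linear epsilon-insensitive SVR and the feedforward DNN are implemented
# here; Lasso and Ridge are backed by glmnet.

BASELINE_NAMES <- c("knn", "random_forest", "xgboost", "lasso", "ridge",
                    "regression_tree", "svr", "dnn")

#' Euclidean distance between two feature vectors
#'
#' \eqn{d(p, q) = \sqrt{\sum_i (q_i - p_i)^2}} -- the metric used by the
#' KNN baseline.
#'
#' @param p,q numeric vectors of equal length
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("length mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  sqrt(sum((q - p)^2))
}

default_hyper <- function(name, p = NULL) {
  switch(name,
    knn             = list(k = 10L),
    random_forest   = list(n_trees = 60L, mtry = NA_integer_, min_node = 5L,
                           max_depth = 30L),
    xgboost         = list(n_rounds = 150L, eta = 0.1, max_depth = 3L,
                           min_node = 10L),
    lasso           = list(lambda = 0.01),
    ridge           = list(lambda = 0.1),
    regression_tree = list(min_node = 5L, max_depth = 30L),
    svr             = list(C = 1, epsilon = 0.1, epochs = 300L, lr = 0.01),
    dnn             = list(hidden = c(64L, 32L), epochs = 60L,
                           batch_size = 64L, lr = 1e-3)
  )
}

#' Baseline learner specification
#'
#' @param name one of `knn`, `random_forest`, `xgboost`, `lasso`, `ridge`,
#'   `regression_tree`, `svr`, `dnn`
#' @param hyper named list of hyperparameters overriding the defaults
#' @param seed RNG seed controlling any stochastic element of fitting
#' @return Object of class `baseline_spec` / `model_spec`.
#' @export
baseline_spec <- function(name, hyper = list(), seed = 1L) {
  if (!name %in% BASELINE_NAMES) {
    stop("unknown model name '", name, "'; valid names: ",
         paste(BASELINE_NAMES, collapse = ", "), call. = FALSE)
  }
  def <- default_hyper(name)
  unknown <- setdiff(names(hyper), names(def))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  def[names(hyper)] <- hyper
  structure(list(name = name, hyper = def, seed = as.integer(seed)),
            class = c(paste0("spec_", name), "baseline_spec", "model_spec"))
}

#' Construct a fit/predict-capable model handle
#'
#' Thin validating constructor around [baseline_spec()]; the returned handle
#' is consumed by [fit_model()].
#'
#' @inheritParams baseline_spec
#' @return A `model_spec` handle.
#' @export
make_baseline <- function(spec) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  spec
}

#' CNN model specification for the unified benchmark interface
#'
#' @param arch a [cnn_arch_config()]
#' @param train_cfg a [train_config()]
#' @param n_weeks weekly series length
#' @param seed seed (overrides `train_cfg$seed` and the init seed)
#' @return A `model_spec` handle of class `spec_cnn`.
#' @export
cnn_spec <- function(arch = cnn_arch_config(), train_cfg = train_config(),
                     n_weeks = 45, seed = 1L) {
  structure(list(name = "cnn", arch = arch, train_cfg = train_cfg,
                 n_weeks = as.integer(n_weeks), seed = as.integer(seed)),
            class = c("spec_cnn", "model_spec"))
}

#' Fit a model handle on a feature matrix
#'
#' @param spec a `model_spec` handle
#' @param x numeric feature matrix (column names define the schema)
#' @param y numeric target vector
#' @param ... unused
#' @return A `trained_model` supporting [predict()].
#' @export
fit_model <- function(spec, x, y, ...) UseMethod("fit_model")

trained <- function(name, spec, x, ...) {
  structure(c(list(name = name, spec = spec,
                   feature_names = colnames(x)), list(...)),
            class = c(paste0("trained_", name), "trained_model"))
}

check_schema <- function(object, x) {
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names)) {
    stop("feature schema mismatch with the training schema", call. = FALSE)
  }
  x
}

# --- KNN ------------------------------------------------------------------

#' @export
fit_model.spec_knn <- function(spec, x, y, ...) {
  k <- spec$hyper$k
  if (k < 1 || k > nrow(x)) stop("knn: k must lie in [1, n_train]", call. = FALSE)
  trained("knn", spec, x, x_train = x, y_train = y)
}

#' @export
predict.trained_knn <- function(object, newdata, ...) {
  x <- check_schema(object, newdata)
  tr <- object$x_train
  k <- object$spec$hyper$k
  d2 <- outer(rowSums(x^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(x)), rowSums(tr^2)) - 2 * tcrossprod(x, tr)
  apply(d2, 1, function(d) mean(object$y_train[order(d)[seq_len(k)]]))
}

# --- trees / forest / boosting -------------------------------------------

fit_tree <- function(x, y, rows, min_node, max_depth, mtry = 0L) {
  cpp_grow_tree(x, y, as.integer(rows - 1L), as.integer(min_node),
                as.integer(max_depth), as.integer(mtry))
}

#' @export
fit_model.spec_regression_tree <- function(spec, x, y, ...) {
  h <- spec$hyper
  set.seed(spec$seed)
  tree <- fit_tree(x, y, seq_len(nrow(x)), h$min_node, h$max_depth)
  trained("regression_tree", spec, x, tree = tree)
}

#' @export
predict.trained_regression_tree <- function(object, newdata, ...) {
  cpp_predict_tree(object$tree, check_schema(object, newdata))
}

#' @export
fit_model.spec_random_forest <- function(spec, x, y, ...) {
  h <- spec$hyper
  n <- nrow(x)
  mtry <- if (is.na(h$mtry)) max(1L, ncol(x) %/% 3L) else as.integer(h$mtry)
  set.seed(spec$seed)
  trees <- lapply(seq_len(h$n_trees), function(b) {
    fit_tree(x, y, sample.int(n, n, replace = TRUE), h$min_node, h$max_depth, mtry)
  })
  trained("random_forest", spec, x, trees = trees)
}

#' @export
predict.trained_random_forest <- function(object, newdata, ...) {
  x <- check_schema(object, newdata)
  preds <- vapply(object$trees, function(tr) cpp_predict_tree(tr, x),
                  numeric(nrow(x)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
fit_model.spec_xgboost <- function(spec, x, y, ...) {
  h <- spec$hyper
  set.seed(spec$seed)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", h$n_rounds)
  for (m in seq_len(h$n_rounds)) {
    tr <- fit_tree(x, resid, seq_len(nrow(x)), h$min_node, h$max_depth)
    resid <- resid - h$eta * cpp_predict_tree(tr, x)
    trees[[m]] <- tr
  }
  trained("xgboost", spec, x, trees = trees, f0 = f0, eta = h$eta)
}

#' @export
predict.trained_xgboost <- function(object, newdata, ...) {
  x <- check_schema(object, newdata)
  out <- rep(object$f0, nrow(x))
  for (tr in object$trees) out <- out + object$eta * cpp_predict_tree(tr, x)
  out
}

# --- penalised linear models (glmnet) -------------------------------------

fit_glmnet <- function(spec, x, y, alpha) {
  lam <- spec$hyper$lambda
  path <- sort(unique(c(exp(seq(log(50), log(1e-7), length.out = 60)), lam)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path)
  trained(spec$name, spec, x, fit = fit, lambda = lam)
}

#' @export
fit_model.spec_lasso <- function(spec, x, y, ...) fit_glmnet(spec, x, y, 1)

#' @export
fit_model.spec_ridge <- function(spec, x, y, ...) fit_glmnet(spec, x, y, 0)

#' @export
predict.trained_lasso <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, check_schema(object, newdata), s = object$lambda))
}

#' @export
predict.trained_ridge <- predict.trained_lasso

# --- linear epsilon-insensitive SVR ---------------------------------------

# Primal objective 0.5 ||w||^2 + C sum_i max(0, |y_i - w'x_i - b| - epsilon),
# minimised by full-batch Adam on the subgradient.
#' @export
fit_model.spec_svr <- function(spec, x, y, ...) {
  h <- spec$hyper
  set.seed(spec$seed)
  params <- list(w = matrix(0, ncol(x), 1), b = mean(y))
  st <- adam_new(params)
  for (ep in seq_len(h$epochs)) {
    r <- y - as.numeric(x %*% params$w + params$b)
    g <- -sign(r) * (abs(r) > h$epsilon)
    grads <- list(w = params$w + h$C * crossprod(x, g), b = h$C * sum(g))
    upd <- adam_step(params, grads, st, h$lr)
    params <- upd$params
    st <- upd$state
  }
  trained("svr", spec, x, w = params$w, b = params$b)
}

#' @export
predict.trained_svr <- function(object, newdata, ...) {
  as.numeric(check_schema(object, newdata) %*% object$w + object$b)
}

# --- DNN baseline ---------------------------------------------------------

#' @export
fit_model.spec_dnn <- function(spec, x, y, ...) {
  h <- spec$hyper
  n_layers <- length(h$hidden) + 1L
  set.seed(spec$seed)
  params <- mlp_init(ncol(x), h$hidden)
  fb <- function(params, idx) {
    A <- mlp_forward(params, x[idx, , drop = FALSE], n_layers)
    r <- as.numeric(A[[n_layers + 1L]]) - y[idx]
    dOut <- matrix(2 * r / length(idx), ncol = 1)
    list(loss = mean(r^2), grads = mlp_backward(params, A, dOut, n_layers))
  }
  res <- sgd_loop(params, nrow(x), h$epochs, h$batch_size, h$lr, spec$seed, fb)
  trained("dnn", spec, x, params = res$params, n_layers = n_layers,
          history = res$history)
}

#' @export
predict.trained_dnn <- function(object, newdata, ...) {
  x <- check_schema(object, newdata)
  A <- mlp_forward(object$params, x, object$n_layers)
  as.numeric(A[[object$n_layers + 1L]])
}

# --- CNN through the unified interface ------------------------------------

#' @export
fit_model.spec_cnn <- function(spec, x, y, ...) {
  model <- build_cnn(spec$arch, n_weeks = spec$n_weeks,
                     n_static = ncol(x) - 6L * spec$n_weeks, seed = spec$seed)
  cfg <- spec$train_cfg
  cfg$seed <- spec$seed
  model <- train_cnn(model, list(x = x, y = y), cfg)
  trained("cnn", spec, x, model = model)
}

#' @export
predict.trained_cnn <- function(object, newdata, ...) {
  predict(object$model, list(x = check_schema(object, newdata)))
}

# --- hyperparameter search -------------------------------------------------

#' Cross-validation search specification
#'
#' @param strategy `"grid"` (full Cartesian product of the candidate sets)
#'   or `"randomized"` (`n_iter` independent draws from the candidate sets)
#' @param space named list; each element the candidate vector (or list) for
#'   one hyperparameter
#' @param n_iter number of randomized-search draws (default 50; the full
#'   field-scale protocol used 1000)
#' @param k_folds number of random cross-validation folds (default 3)
#' @param seed seed for fold assignment and candidate sampling
#' @return Object of class `search_spec`.
#' @export
search_spec <- function(strategy = c("randomized", "grid"), space,
                        n_iter = 50L, k_folds = 3L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(space) == 0) stop("empty search space", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  structure(list(strategy = strategy, space = space,
                 n_iter = as.integer(n_iter), k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "search_spec")
}

sample_candidates <- function(search) {
  space <- lapply(search$space, function(v) if (is.list(v)) v else as.list(v))
  if (search$strategy == "grid") {
    grid <- expand.grid(lapply(space, seq_along))
    cand <- lapply(seq_len(nrow(grid)), function(i) {
      stats::setNames(lapply(names(space), function(nm) space[[nm]][[grid[i, nm]]]),
                      names(space))
    })
  } else {
    cand <- lapply(seq_len(search$n_iter), function(i) {
      stats::setNames(lapply(space, function(v) v[[sample.int(length(v), 1)]]),
                      names(space))
    })
    cand <- unique(cand)
  }
  cand
}

#' Cross-validated hyperparameter search
#'
#' Random (seeded) fold assignment over training rows; every candidate is
#' scored by mean out-of-fold RMSE; the minimiser is returned together with
#' the full trial log.
#'
#' @param name baseline model name (see [baseline_spec()])
#' @param search a [search_spec()]
#' @param x,y training feature matrix and target
#' @return List with `best` (hyperparameter list), `best_score`, and
#'   `trials` (data.frame log, one row per candidate).
#' @export
tune_hyperparameters <- function(name, search, x, y) {
  stopifnot(inherits(search, "search_spec"))
  n <- nrow(x)
  if (n < search$k_folds) stop("fewer rows than folds", call. = FALSE)
  set.seed(search$seed)
  folds <- sample(rep(seq_len(search$k_folds), length.out = n))
  cands <- sample_candidates(search)
  scores <- numeric(length(cands))
  for (ci in seq_along(cands)) {
    rmse_k <- numeric(search$k_folds)
    for (k in seq_len(search$k_folds)) {
      tr <- folds != k
      spec <- baseline_spec(name, hyper = cands[[ci]], seed = search$seed)
      fit <- fit_model(spec, x[tr, , drop = FALSE], y[tr])
      p <- predict(fit, x[!tr, , drop = FALSE])
      rmse_k[k] <- sqrt(mean((p - y[!tr])^2))
    }
    scores[ci] <- mean(rmse_k)
  }
  trials <- cbind(
    do.call(rbind, lapply(cands, function(cc) {
      as.data.frame(lapply(cc, function(v) {
        if (length(v) > 1) paste(v, collapse = "|") else v
      }))
    })),
    mean_cv_rmse = scores)
  best <- which.min(scores)
  list(best = cands[[best]], best_score = scores[best], trials = trials)
}

#' Default search spaces for the baseline learners
#'
#' Deliberately small, desk-scale candidate sets; the search protocol (not
#' the candidate values) is the reproducible content, and every value is
#' overridable.
#'
#' @param name baseline model name
#' @return Named list of candidate vectors.
#' @export
default_search_space <- function(name) {
  switch(name,
    knn             = list(k = c(3L, 5L, 10L, 20L, 40L)),
    random_forest   = list(n_trees = c(30L, 60L), min_node = c(3L, 5L, 10L),
                           max_depth = c(10L, 30L)),
    xgboost         = list(n_rounds = c(75L, 150L), eta = c(0.05, 0.1, 0.2),
                           max_depth = c(2L, 3L, 4L)),
    lasso           = list(lambda = 10^seq(-4, 0, by = 0.5)),
    ridge           = list(lambda = 10^seq(-3, 1, by = 0.5)),
    regression_tree = list(min_node = c(3L, 5L, 10L, 20L),
                           max_depth = c(5L, 10L, 30L)),
    svr             = list(C = c(0.3, 1, 3), epsilon = c(0.05, 0.1, 0.2)),
    dnn             = list(hidden = list(c(32L), c(64L, 32L), c(128L, 64L)),
                           lr = c(1e-3, 3e-3)),
    stop("unknown model name '", name, "'", call. = FALSE)
  )
}
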
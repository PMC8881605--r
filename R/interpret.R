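# Model-agnostic Kernel SHAP explanation and the Shapley-ranked
# feature-selection ablation.
#
# Kernel SHAP estimates Shapley values by a weighted least-squares fit over
# feature coalitions: masked-out features are integrated over a background
# sample, coalition weights follow the Shapley kernel
# (M - 1) / (choose(M, s) * s * (M - s)), and the local-accuracy constraint
# (contributions sum to prediction minus base value) is imposed exactly by
# eliminating one coefficient. Small feature spaces are enumerated exactly;
# large ones enumerate complete coalition-size groups (sizes 1 and M-1
# first) and sample the remainder.

coalition_design <- function(M, budget, seed) {
  sizes <- seq_len(M - 1)
  mass <- (M - 1) / (sizes * (M - sizes))
  mass <- mass / sum(mass)

  Zs <- list(); ws <- c()
  remaining <- budget
  # pair sizes from the outside in: 1, M-1, 2, M-2, ...
  s_order <- unique(as.vector(rbind(sizes[sizes <= (M - 1) / 2 + 1e-9],
                                    rev(sizes)[sizes <= (M - 1) / 2 + 1e-9])))
  s_order <- unique(c(s_order, sizes))
  enumerated <- logical(M - 1)
  for (s in s_order) {
    cnt <- choose(M, s)
    if (cnt > remaining || cnt > 2e4) next
    combs <- utils::combn(M, s)
    Zblk <- matrix(0, ncol(combs), M)
    Zblk[cbind(rep(seq_len(ncol(combs)), each = s), as.vector(combs))] <- 1
    Zs[[length(Zs) + 1L]] <- Zblk
    ws <- c(ws, rep(mass[s] / cnt, ncol(combs)))
    enumerated[s] <- TRUE
    remaining <- remaining - cnt
    if (remaining <= 0) break
  }
  if (remaining > 0 && any(!enumerated)) {
    # paired (antithetic) sampling: every drawn coalition is added together
    # with its complement, halving estimator variance at no extra cost
    rem_sizes <- sizes[!enumerated]
    rem_mass <- mass[!enumerated]
    n_pair <- ceiling(remaining / 2)
    pick <- sample(rem_sizes, n_pair, replace = TRUE,
                   prob = rem_mass / sum(rem_mass))
    Zblk <- matrix(0, 2 * n_pair, M)
    for (i in seq_len(n_pair)) {
      on <- sample.int(M, pick[i])
      Zblk[2 * i - 1, on] <- 1
      Zblk[2 * i, -on] <- 1
    }
    Zs[[length(Zs) + 1L]] <- Zblk
    ws <- c(ws, rep(sum(rem_mass) / (2 * n_pair), 2 * n_pair))
  }
  list(Z = do.call(rbind, Zs), w = ws)
}

as_matrix_input <- function(x) {
  if (inherits(x, "feature_table")) x$x else as.matrix(x)
}

#' Kernel SHAP contributions
#'
#' @param predict_fn function taking a feature matrix and returning a
#'   numeric prediction vector (see [model_predict_fn()])
#' @param background `feature_table` or matrix of background rows (the
#'   reference distribution masked-out features are integrated over);
#'   documented field-scale default is ~100 rows
#' @param instances `feature_table` or matrix of rows to explain
#' @param budget number of coalitions per instance (default `2 * M + 48`)
#' @param seed RNG seed for coalition sampling
#' @param ridge small Tikhonov stabiliser for the WLS solve
#' @return Object of class `shap_matrix`: list with `contributions`
#'   (instances x features, t/ha), `base_value` (mean background
#'   prediction), `prediction` (per explained instance), `budget`,
#'   `n_background`. Local accuracy `base + rowSums(contributions) ==
#'   prediction` holds by construction.
#' @export
shap_values <- function(predict_fn, background, instances, budget = NULL,
                        seed = 1L, ridge = 1e-6) {
  BG <- as_matrix_input(background)
  X <- as_matrix_input(instances)
  if (!identical(colnames(BG), colnames(X))) {
    stop("schema mismatch between background and instances", call. = FALSE)
  }
  M <- ncol(X)
  if (is.null(budget)) budget <- 2L * M + 48L
  set.seed(seed)

  full <- 2^M - 2
  des <- if (M <= 20 && full <= budget) {
    # exact enumeration of every proper coalition
    Z <- as.matrix(expand.grid(rep(list(0:1), M)))[-c(1, 2^M), , drop = FALSE]
    colnames(Z) <- NULL
    s <- rowSums(Z)
    list(Z = Z, w = (M - 1) / (choose(M, s) * s * (M - s)))
  } else {
    coalition_design(M, budget, seed)
  }
  Z <- des$Z
  w <- des$w
  nc <- nrow(Z)
  B <- nrow(BG)

  base <- mean(predict_fn(BG))
  fx <- as.numeric(predict_fn(X))

  # shared WLS solve: eliminate the last feature to impose local accuracy
  A <- Z[, -M, drop = FALSE] - Z[, M]
  Aw <- A * w
  H <- solve(crossprod(A, Aw) + diag(ridge, M - 1), t(Aw))

  phi <- matrix(0, nrow(X), M, dimnames = list(NULL, colnames(X)))
  # one masked-input block per instance: rows are (coalition, background) pairs
  Mrep <- Z[rep(seq_len(nc), each = B), , drop = FALSE]
  tile <- BG[rep(seq_len(B), times = nc), , drop = FALSE] * (1 - Mrep)
  nr <- nrow(Mrep)
  for (i in seq_len(nrow(X))) {
    Xi <- tile + Mrep * rep(X[i, ], each = nr)
    colnames(Xi) <- colnames(X)
    v <- colMeans(matrix(predict_fn(Xi), nrow = B))
    yi <- v - base - Z[, M] * (fx[i] - base)
    ph <- as.numeric(H %*% yi)
    phi[i, ] <- c(ph, fx[i] - base - sum(ph))
  }
  structure(list(contributions = phi, base_value = base, prediction = fx,
                 budget = nc, n_background = B),
            class = "shap_matrix")
}

#' Prediction closure for a trained model
#'
#' Wraps a `trained_model` (or `cnn_model`) into the plain
#' `matrix -> numeric` function consumed by [shap_values()].
#'
#' @param model a `trained_model` or `cnn_model`
#' @param feature_names column names to stamp onto incoming matrices
#' @return A function of one matrix argument.
#' @export
model_predict_fn <- function(model, feature_names = NULL) {
  fn <- feature_names %||% model$feature_names
  function(x) {
    x <- as.matrix(x)
    colnames(x) <- fn
    if (inherits(model, "cnn_model")) predict(model, list(x = x))
    else predict(model, x)
  }
}

#' Global feature importance from SHAP contributions
#'
#' Importance is the column mean of absolute contributions; the sign is the
#' Pearson correlation sign between feature values and contributions
#' (features positively/negatively associated with their yield impact);
#' ranks are a permutation of 1..n_features (ties broken by column order).
#'
#' @param shap a `shap_matrix`
#' @param features the explained instances' feature values
#'   (`feature_table` or matrix; same rows as the shap matrix)
#' @return Object of class `importance_table`: data.frame with `feature`,
#'   `importance`, `sign`, `rank`.
#' @export
global_importance <- function(shap, features) {
  stopifnot(inherits(shap, "shap_matrix"))
  X <- as_matrix_input(features)
  phi <- shap$contributions
  if (nrow(phi) == 0) stop("empty shap matrix", call. = FALSE)
  stopifnot(nrow(X) == nrow(phi), ncol(X) == ncol(phi))
  imp <- colMeans(abs(phi))
  sgn <- vapply(seq_len(ncol(phi)), function(j) {
    if (sd(X[, j]) == 0 || sd(phi[, j]) == 0) return(0)
    sign(cor(X[, j], phi[, j]))
  }, numeric(1))
  out <- data.frame(feature = colnames(phi), importance = unname(imp),
                    sign = sgn, row.names = NULL)
  out$rank <- rank(-out$importance, ties.method = "first")
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top-k slice of an importance table
#'
#' @param importance an `importance_table`
#' @param k number of features (default 15)
#' @return The k highest-ranked rows, in rank order.
#' @export
top_features <- function(importance, k = 15) {
  stopifnot(inherits(importance, "importance_table"))
  imp <- importance[order(importance$rank), ]
  imp[seq_len(min(k, nrow(imp))), ]
}

#' Force-plot data for one explained instance
#'
#' Selects the instance with the minimum, median or maximum actual yield
#' (median of an even-sized set = the lower of the two middle yields) and
#' returns its signed contributions sorted by magnitude, together with the
#' base and output values; `base + sum(contributions) == output`.
#'
#' @param shap a `shap_matrix`
#' @param actual actual yields of the explained instances
#' @param selector `"min"`, `"median"` or `"max"`
#' @return List with `selector`, `instance` (row index), `actual`,
#'   `base_value`, `output_value`, and `contributions` (data.frame feature /
#'   contribution / direction, sorted by |contribution| descending).
#' @export
force_data <- function(shap, actual, selector = c("min", "median", "max")) {
  stopifnot(inherits(shap, "shap_matrix"))
  selector <- match.arg(selector)
  n <- length(actual)
  if (n == 0) stop("empty instance set", call. = FALSE)
  stopifnot(n == nrow(shap$contributions))
  idx <- switch(selector,
                min = which.min(actual),
                max = which.max(actual),
                median = order(actual)[ceiling(n / 2)])
  contrib <- shap$contributions[idx, ]
  ord <- order(-abs(contrib))
  list(selector = selector, instance = idx, actual = actual[idx],
       base_value = shap$base_value,
       output_value = shap$prediction[idx],
       contributions = data.frame(
         feature = names(contrib)[ord],
         contribution = unname(contrib[ord]),
         direction = ifelse(contrib[ord] >= 0, "positive", "negative"),
         row.names = NULL))
}

#' Weekly weather importance profile
#'
#' Aggregates mean absolute contributions over the `<Variable>_<week>`
#' weather columns into a (variable x week) grid; per-variable totals are
#' normalised to sum to 100 across all weather features (percent of total
#' weather importance).
#'
#' @param shap a `shap_matrix`
#' @return List with `grid` (long data.frame variable/week/importance) and
#'   `totals` (named vector summing to 100).
#' @export
weekly_weather_profile <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  cols <- colnames(shap$contributions)
  pat <- paste0("^(", paste(weather_variables(), collapse = "|"), ")_(\\d+)$")
  sel <- grepl(pat, cols)
  if (!any(sel)) stop("no weather columns of the form <Variable>_<week> found",
                      call. = FALSE)
  imp <- colMeans(abs(shap$contributions[, sel, drop = FALSE]))
  variable <- sub(pat, "\\1", cols[sel])
  week <- as.integer(sub(pat, "\\2", cols[sel]))
  grid <- data.frame(variable = variable, week = week,
                     importance = unname(imp), row.names = NULL)
  tot <- tapply(grid$importance, grid$variable, sum)
  tot <- stats::setNames(as.numeric(tot), names(tot))  # drop 1-d array dims
  total_all <- sum(grid$importance)
  totals <- if (total_all == 0) tot * 0 else 100 * tot / total_all
  # report in canonical variable order
  totals <- totals[intersect(weather_variables(), names(totals))]
  list(grid = grid[order(grid$variable, grid$week), ], totals = totals)
}

#' Importance-ranked feature-selection ablation
#'
#' Retrains a model on nested feature subsets -- the full set, the top
#' `ceiling(fraction * p)` features by Shapley rank, and optionally the
#' weekly weather columns only -- under the year-wise hold-out protocol,
#' reporting RMSE / MAE / r per subset and test year. For CNN specs the
#' excluded columns are masked to 0 (the post-standardisation training
#' mean) so the convolutional input layout is preserved; tabular models
#' drop the columns outright.
#'
#' @param model_builder a `model_spec`, or a function
#'   `function(feature_names) -> model_spec`
#' @param table unstandardised `feature_table` with yield
#' @param importance an `importance_table` covering every column of `table`
#' @param test_years hold-out years
#' @param fractions numeric fractions in (0, 1] (default `c(1, 0.75, 0.5)`)
#' @param weather_only also run the weather-columns-only subset?
#' @return data.frame with subset, n_features, test_year, partition and
#'   metric columns.
#' @export
ablation_retrain <- function(model_builder, table, importance, test_years,
                             fractions = c(1, 0.75, 0.5), weather_only = TRUE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(importance, "importance_table"))
  p <- ncol(table$x)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!all(colnames(table$x) %in% importance$feature)) {
    stop("importance table does not cover all feature columns", call. = FALSE)
  }
  ranked <- importance$feature[order(importance$rank)]

  subsets <- lapply(fractions, function(f) {
    keep <- ranked[seq_len(ceiling(f * p))]
    list(label = if (f == 1) "full" else paste0("top_", round(100 * f), "pct"),
         keep = keep)
  })
  if (weather_only) {
    wk <- grep(paste0("^(", paste(weather_variables(), collapse = "|"), ")_\\d+$"),
               colnames(table$x), value = TRUE)
    subsets <- c(subsets, list(list(label = "weather_only", keep = wk)))
  }

  rows <- list()
  for (sub in subsets) {
    keep <- colnames(table$x)[colnames(table$x) %in% sub$keep]
    for (ty in test_years) {
      sp <- temporal_split(table, ty)
      norm <- fit_normalizer(sp$train)
      trn <- apply_normalizer(sp$train, norm)
      ten <- apply_normalizer(sp$test, norm)
      spec <- if (is.function(model_builder)) model_builder(keep) else model_builder
      if (inherits(spec, "spec_cnn")) {
        # mask excluded columns at their (standardised) training mean of 0
        drop <- setdiff(colnames(trn$x), keep)
        trn$x[, drop] <- 0
        ten$x[, drop] <- 0
        xtr <- trn$x; xte <- ten$x
      } else {
        xtr <- trn$x[, keep, drop = FALSE]
        xte <- ten$x[, keep, drop = FALSE]
      }
      fit <- fit_model(spec, xtr, trn$y)
      for (part in c("train", "test")) {
        xx <- if (part == "train") xtr else xte
        yy <- if (part == "train") trn$y else ten$y
        m <- compute_metrics(yy, predict(fit, xx))
        rows[[length(rows) + 1L]] <- data.frame(
          subset = sub$label, n_features = length(keep), test_year = ty,
          partition = part, rmse = m$rmse, mae = m$mae, r = m$r,
          pearson = m$pearson)
      }
    }
  }
  do.call(rbind, rows)
}
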
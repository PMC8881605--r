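# Evaluation metrics, residual normality diagnostics, and the multi-model /
# multi-test-year benchmark harness.

#' Compute MAE, RMSE and the root-of-R2 correlation metric
#'
#' MAE and RMSE are the usual mean absolute / root mean squared errors. The
#' headline correlation metric is the square root of `1 - SSE/SST` as used
#' in this modelling tradition -- note this is NOT the Pearson correlation,
#' which is reported alongside as `pearson`. When `SST = 0` (constant
#' actuals) or the radicand is negative (`SSE > SST`, a model worse than
#' the mean) `r` is returned as `NA` with `r_flag` explaining why.
#'
#' @param actual,predicted numeric vectors of equal, nonzero length
#' @return Object of class `evaluation_result`: list with `mae`, `rmse`,
#'   `r`, `r_flag`, `pearson`, `n`, `residuals` (actual - predicted).
#' @export
compute_metrics <- function(actual, predicted) {
  if (length(actual) == 0) stop("empty input", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop("length mismatch: ", length(actual), " vs ", length(predicted),
         call. = FALSE)
  }
  res <- actual - predicted
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  sse <- sum(res^2)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) {
    r <- NA_real_; flag <- "undefined: SST = 0 (constant actuals)"
  } else if (sse > sst) {
    r <- NA_real_; flag <- "undefined: negative radicand (SSE > SST)"
  } else {
    r <- sqrt(1 - sse / sst); flag <- "ok"
  }
  pear <- if (sst == 0 || sd(predicted) == 0) NA_real_ else cor(actual, predicted)
  structure(list(mae = mae, rmse = rmse, r = r, r_flag = flag,
                 pearson = pear, n = length(actual), residuals = res),
            class = "evaluation_result")
}

#' @exportS3Method base::print
print.evaluation_result <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.4f  RMSE = %.4f  r = %s  (pearson = %s)\n",
              x$n, x$mae, x$rmse,
              if (is.na(x$r)) paste0("NA [", x$r_flag, "]") else sprintf("%.4f", x$r),
              if (is.na(x$pearson)) "NA" else sprintf("%.4f", x$pearson)))
  invisible(x)
}

#' Per-instance absolute percentage error
#'
#' `|(A_i - P_i) / A_i| * 100`; elements with `A_i = 0` are returned as
#' `NA` (flagged undefined) rather than infinity.
#'
#' @param actual,predicted numeric vectors of equal length
#' @return Numeric vector of percentages (NA where actual is zero).
#' @export
percentage_error <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("length mismatch", call. = FALSE)
  }
  out <- abs((actual - predicted) / actual) * 100
  out[actual == 0] <- NA_real_
  out
}

# Anderson-Darling normality test (composite: mean and variance estimated),
# with the small-sample correction and the Stephens / D'Agostino p-value
# approximation. Implemented here because no normality-test add-on package
# is available in the target environment.
anderson_darling <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  eps <- .Machine$double.xmin
  p <- pmin(pmax(p, eps), 1 - 1e-16)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  A2s <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  pval <- if (A2s >= 0.6) {
    exp(1.2937 - 5.709 * A2s + 0.0186 * A2s^2)
  } else if (A2s >= 0.34) {
    exp(0.9177 - 4.279 * A2s - 1.38 * A2s^2)
  } else if (A2s >= 0.2) {
    1 - exp(-8.318 + 42.796 * A2s - 59.938 * A2s^2)
  } else {
    1 - exp(-13.436 + 101.14 * A2s - 223.73 * A2s^2)
  }
  list(statistic = A2s, p_value = min(max(pval, 0), 1))
}

#' Residual normality diagnostics
#'
#' Shapiro-Wilk and Anderson-Darling tests of the residual vector, with an
#' accept/reject decision at `alpha`.
#'
#' @param residuals numeric vector, length >= 8, non-constant
#' @param alpha significance level (default 0.05)
#' @return data.frame with one row per test: `test`, `statistic`, `p_value`,
#'   `normal` (logical decision at `alpha`).
#' @export
residual_normality <- function(residuals, alpha = 0.05) {
  n <- length(residuals)
  if (n < 8) stop("need at least 8 residuals (got ", n, ")", call. = FALSE)
  if (sd(residuals) == 0) stop("constant residuals", call. = FALSE)
  # shapiro.test caps n at 5000; subsample deterministically if larger
  xs <- if (n > 5000) residuals[round(seq(1, n, length.out = 5000))] else residuals
  sw <- stats::shapiro.test(xs)
  ad <- anderson_darling(residuals)
  data.frame(
    test = c("shapiro_wilk", "anderson_darling"),
    statistic = c(unname(sw$statistic), ad$statistic),
    p_value = c(sw$p.value, ad$p_value),
    normal = c(sw$p.value, ad$p_value) > alpha
  )
}

#' Benchmark a set of models over year-wise hold-out splits
#'
#' For every (model, test year): train on all years strictly before the
#' test year (normaliser fitted on those training rows only), evaluate on
#' the held-out year, and report train and test MAE / RMSE / r. Optional
#' per-model hyperparameter search runs inside each training partition.
#'
#' @param models named list of `model_spec` handles (see [baseline_spec()],
#'   [cnn_spec()])
#' @param table an unstandardised `feature_table` with yield
#' @param test_years integer vector of hold-out years
#' @param tune named list mapping model names to [search_spec()]s (optional)
#' @param keep_predictions also return per-instance test predictions
#' @return Object of class `benchmark_result`: list with `grid` (long
#'   data.frame), `tuned` (chosen hyperparameters) and optionally
#'   `predictions`.
#' @export
benchmark <- function(models, table, test_years, tune = NULL,
                      keep_predictions = FALSE) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$y))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list", call. = FALSE)
  }
  grid <- list()
  tuned <- list()
  preds <- list()
  for (ty in test_years) {
    sp <- temporal_split(table, ty)
    norm <- fit_normalizer(sp$train)
    trn <- apply_normalizer(sp$train, norm)
    ten <- apply_normalizer(sp$test, norm)
    for (mn in names(models)) {
      spec <- models[[mn]]
      if (!is.null(tune[[mn]]) && inherits(spec, "baseline_spec")) {
        tr <- tune_hyperparameters(spec$name, tune[[mn]], trn$x, trn$y)
        spec <- baseline_spec(spec$name, hyper = tr$best, seed = spec$seed)
        tuned[[paste(mn, ty, sep = "_")]] <- tr$best
      }
      fit <- fit_model(spec, trn$x, trn$y)
      for (part in c("train", "test")) {
        tab <- if (part == "train") trn else ten
        m <- compute_metrics(tab$y, predict(fit, tab$x))
        grid[[length(grid) + 1L]] <- data.frame(
          model = mn, test_year = ty, partition = part,
          rmse = m$rmse, mae = m$mae, r = m$r, pearson = m$pearson, n = m$n)
      }
      if (keep_predictions) {
        pr <- predict(fit, ten$x)
        preds[[paste(mn, ty, sep = "_")]] <- data.frame(
          model = mn, test_year = ty, ten$keys,
          actual = ten$y, predicted = pr,
          pct_error = percentage_error(ten$y, pr))
      }
    }
  }
  out <- list(grid = do.call(rbind, grid), tuned = tuned)
  if (keep_predictions) out$predictions <- do.call(rbind, preds)
  structure(out, class = "benchmark_result")
}

#' Reshape a benchmark grid into the wide models-by-rows layout
#'
#' One row per (partition, test year, metric), one column per model.
#'
#' @param bench a `benchmark_result`
#' @return A wide data.frame.
#' @export
benchmark_wide <- function(bench) {
  g <- bench$grid
  rows <- list()
  for (metric in c("rmse", "mae", "r")) {
    for (ty in sort(unique(g$test_year))) {
      for (part in c("train", "test")) {
        sel <- g[g$test_year == ty & g$partition == part, ]
        vals <- stats::setNames(as.list(sel[[metric]]), sel$model)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(metric = metric, partition = part, test_year = ty),
          as.data.frame(vals))
      }
    }
  }
  do.call(rbind, rows)
}
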
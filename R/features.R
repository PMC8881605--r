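# Feature assembly, z-score standardisation and the year-wise hold-out split.

#' Aggregate a daily series to weekly means
#'
#' Week k is the mean of days 7(k-1)+1 ... 7k. Trailing days that do not
#' fill a whole week are merged into the final week, which is then averaged
#' over its actual length -- so 365 daily values give 52 weeks, the last
#' averaging 8 days, matching the 365:52 weekly reduction. Series shorter
#' than a week yield one week averaged over the available days.
#'
#' @param daily numeric vector of daily values (length >= 1)
#' @return Numeric vector of weekly means.
#' @export
aggregate_daily_to_weekly <- function(daily) {
  n <- length(daily)
  if (n == 0) stop("empty daily series", call. = FALSE)
  k <- max(1L, n %/% 7L)
  week <- pmin((seq_len(n) - 1L) %/% 7L + 1L, k)
  as.numeric(tapply(daily, week, mean))
}

#' Assemble the model-ready feature table from a panel
#'
#' Produces the fixed-order feature matrix: `6 * n_weeks` weekly weather
#' columns (`<Variable>_<week>`, variable-major) followed by the seven
#' static columns `SowingDOY, FloweringDOY, HarvestDOY, LL, DUL, SAT, BD` --
#' 277 columns at the default 45 weeks. The yield vector and (county, year)
#' row keys ride along.
#'
#' @param panel a `panel_table`
#' @return An object of class `feature_table`: list with `x` (numeric
#'   matrix), `y` (numeric or NULL), `keys` (data.frame county_id, year),
#'   `n_weeks`.
#' @export
assemble_feature_table <- function(panel) {
  stopifnot(inherits(panel, "panel_table"))
  dat <- panel$data
  if (nrow(dat) == 0) stop("empty panel", call. = FALSE)
  cols <- c(weather_column_names(panel$n_weeks), static_columns())
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(head(missing_cols, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(dat[, cols])
  bad <- which(!stats::complete.cases(x) | rowSums(!is.finite(x)) > 0)
  if (length(bad)) {
    k <- bad[1]
    stop("malformed weather/static values in row (",
         dat$county_id[k], ", ", dat$year[k], ")", call. = FALSE)
  }
  y <- if ("Yield" %in% names(dat)) dat$Yield else NULL
  structure(list(x = x, y = y,
                 keys = dat[, c("county_id", "year")],
                 n_weeks = panel$n_weeks),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$x), "instances x", ncol(x$x), "features",
      if (is.null(x$y)) "(no yield)" else "", "\n")
  invisible(x)
}

# internal constructor used when subsetting
feature_table <- function(x, y, keys, n_weeks) {
  structure(list(x = x, y = y, keys = keys, n_weeks = n_weeks),
            class = "feature_table")
}

subset_rows <- function(table, idx) {
  feature_table(table$x[idx, , drop = FALSE],
                if (is.null(table$y)) NULL else table$y[idx],
                table$keys[idx, , drop = FALSE],
                table$n_weeks)
}

subset_cols <- function(table, cols) {
  feature_table(table$x[, cols, drop = FALSE], table$y, table$keys, table$n_weeks)
}

#' Fit z-score normalization parameters on a training table
#'
#' Per-feature mean and population standard deviation (divisor n, matching
#' the plain z-score definition), computed over training rows only.
#'
#' @param train a `feature_table`
#' @param sd_type `"population"` (default) or `"sample"`
#' @return Object of class `normalization_params` with `mu`, `sigma`, and
#'   the fitted-on row keys.
#' @export
fit_normalizer <- function(train, sd_type = c("population", "sample")) {
  stopifnot(inherits(train, "feature_table"))
  sd_type <- match.arg(sd_type)
  n <- nrow(train$x)
  if (n == 0) stop("empty training table", call. = FALSE)
  mu <- colMeans(train$x)
  ss <- colMeans(train$x^2) - mu^2
  ss[ss < 0] <- 0
  sigma <- sqrt(ss)
  if (sd_type == "sample" && n > 1) sigma <- sigma * sqrt(n / (n - 1))
  structure(list(mu = mu, sigma = sigma, sd_type = sd_type,
                 fitted_keys = train$keys),
            class = "normalization_params")
}

#' Apply (or invert) z-score normalization
#'
#' Each value becomes `(x - mu_j) / sigma_j`. Constant columns
#' (`sigma_j = 0`) map to 0 and emit one warning rather than an error.
#'
#' @param table a `feature_table`
#' @param params a `normalization_params` fitted with [fit_normalizer()]
#' @param invert undo the transform (`mu + sigma * x`) instead
#' @return A new `feature_table` on the transformed scale.
#' @export
apply_normalizer <- function(table, params, invert = FALSE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(params, "normalization_params"))
  have <- colnames(table$x)
  want <- names(params$mu)
  if (!identical(have, want)) {
    stop("column mismatch: missing [",
         paste(head(setdiff(want, have), 5), collapse = ", "),
         "], extra [", paste(head(setdiff(have, want), 5), collapse = ", "), "]",
         call. = FALSE)
  }
  sig <- params$sigma
  zero <- sig == 0
  if (any(zero) && !invert) {
    warning(sum(zero), " constant column(s) (sigma = 0) mapped to 0",
            call. = FALSE)
  }
  x <- table$x
  if (invert) {
    x <- sweep(sweep(x, 2, sig, `*`), 2, params$mu, `+`)
  } else {
    s <- ifelse(zero, 1, sig)
    x <- sweep(sweep(x, 2, params$mu, `-`), 2, s, `/`)
    if (any(zero)) x[, zero] <- 0
  }
  feature_table(x, table$y, table$keys, table$n_weeks)
}

#' Year-wise (non-random) hold-out split
#'
#' Training rows are all years strictly before `test_year`; test rows are
#' exactly `test_year`. This is the temporal protocol that forbids
#' retroactive prediction.
#'
#' @param table a `feature_table`
#' @param test_year integer year present in the table
#' @return List with `train` and `test` feature tables.
#' @export
temporal_split <- function(table, test_year) {
  stopifnot(inherits(table, "feature_table"))
  yrs <- table$keys$year
  if (!test_year %in% yrs) {
    stop("test_year ", test_year, " not present in the table", call. = FALSE)
  }
  tr <- which(yrs < test_year)
  te <- which(yrs == test_year)
  if (!length(tr)) {
    stop("degenerate split: no training years precede ", test_year, call. = FALSE)
  }
  list(train = subset_rows(table, tr), test = subset_rows(table, te))
}

#' Write a feature table to CSV
#'
#' @param table a `feature_table`
#' @param path output path
#' @return Invisibly, the path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$keys, as.data.frame(table$x))
  if (!is.null(table$y)) df$Yield <- table$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
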
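# Synthetic county-year panel generator.
#
# Emulates the structure of a national winter-wheat panel: for every
# (county, year) a 6 x n_weeks block of season-relative weekly weather
# (week 1 = first week after sowing), four static soil water-retention
# properties constant per county, three phenology dates jittered by year,
# and a yield computed from a documented ground-truth response so that
# downstream feature-importance recovery can be checked against a known
# driver set.

#' Per-variable weather generation parameters
#'
#' Each weekly series is simulated as a seasonal cosine mean curve plus a
#' county random effect, a year anomaly, and AR(1) weekly noise:
#' \deqn{x_{c,y,w} = base + amp \cos(2\pi (w - peak)/52) + a_c + b_y + e_w}
#' with \eqn{e_w = \phi e_{w-1} + \eta_w}, \eqn{\eta_w \sim N(0, innovation\_sd^2)}
#' started from the stationary distribution. Non-negative variables are
#' truncated at zero; relative humidity is clipped to [0, 100].
#'
#' @param base seasonal mean level (variable units)
#' @param amp seasonal amplitude
#' @param peak_week season-relative week of the seasonal maximum
#' @param county_sd SD of the per-county level shift
#' @param year_sd SD of the per-year anomaly
#' @param ar1 AR(1) coefficient, must lie in (-1, 1)
#' @param innovation_sd SD of the AR(1) innovations
#' @param lower,upper truncation bounds (NA for none)
#' @return A list of class `weather_var_params`.
#' @export
weather_var_params <- function(base, amp, peak_week, county_sd, year_sd,
                               ar1, innovation_sd, lower = NA, upper = NA) {
  if (!is.finite(ar1) || ar1 <= -1 || ar1 >= 1) {
    stop("configuration error: ar1 must lie in (-1, 1)", call. = FALSE)
  }
  if (innovation_sd < 0 || county_sd < 0 || year_sd < 0) {
    stop("configuration error: weather SDs must be non-negative", call. = FALSE)
  }
  structure(list(base = base, amp = amp, peak_week = peak_week,
                 county_sd = county_sd, year_sd = year_sd, ar1 = ar1,
                 innovation_sd = innovation_sd, lower = lower, upper = upper),
            class = "weather_var_params")
}

default_weather_params <- function() {
  list(
    Wind          = weather_var_params(3.8, 0.8, 14, 0.25, 0.10, 0.30, 0.6, lower = 0),
    Tmin          = weather_var_params(5.0, 7.0, 40, 0.50, 0.40, 0.30, 1.8),
    Tmax          = weather_var_params(12.0, 9.0, 40, 0.50, 0.40, 0.30, 2.0),
    Humidity      = weather_var_params(77, 8, 13, 1.5, 1.0, 0.30, 4.0, lower = 0, upper = 100),
    Precipitation = weather_var_params(13, 3, 38, 1.5, 1.0, 0.25, 7.0, lower = 0),
    Radiation     = weather_var_params(10, 8, 40, 0.40, 0.30, 0.30, 2.2, lower = 0)
  )
}

#' Ground-truth yield response specification
#'
#' The documented data-generating yield model:
#' \deqn{y = baseline + \sum_d t_d + DUL\ term + a_c + trend (year - year_0) + \varepsilon}
#' where each driver term \eqn{t_d} acts on the mean of one weather variable
#' over a window of season-relative weeks: `linear` terms are
#' `weight * mean`, `hinge_below` terms are `-weight * max(0, threshold - mean)`
#' (a deficit penalty) and `hinge_above` terms are
#' `-weight * max(0, mean - threshold)` (an excess penalty). The soil term is
#' a piecewise-linear penalty `-dul_penalty * max(0, dul_breakpoint - DUL)`,
#' reflecting reduced water-holding capacity below field capacity of
#' 0.27 cm3/cm3. The nonzero driver set is recorded and queryable via
#' [truth_features()].
#'
#' @param baseline_yield intercept, t/ha
#' @param driver_weights list of driver terms; each a list with elements
#'   `variable` (one of [weather_variables()]), `weeks` (integer window),
#'   `weight` (t/ha per variable unit), `form` ("linear", "hinge_below",
#'   "hinge_above") and `threshold` (hinges only, variable units)
#' @param dul_breakpoint DUL breakpoint, cm3/cm3
#' @param dul_penalty t/ha per cm3/cm3 of DUL deficit below the breakpoint
#' @param county_effect_sd SD of the county yield effect, t/ha
#' @param year_trend linear technology trend, t/ha per year
#' @param noise_sd residual SD, t/ha
#' @return A list of class `yield_truth`.
#' @export
yield_truth <- function(baseline_yield = 9.3,
                        driver_weights = default_driver_weights(),
                        dul_breakpoint = 0.27,
                        dul_penalty = 14,
                        county_effect_sd = 0.20,
                        year_trend = 0.02,
                        noise_sd = 0.20) {
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  for (d in driver_weights) {
    stopifnot(is.list(d), !is.null(d$variable), !is.null(d$weeks), !is.null(d$weight))
    if (!d$variable %in% weather_variables()) {
      stop("configuration error: unknown driver variable '", d$variable, "'",
           call. = FALSE)
    }
    d$form <- d$form %||% "linear"
    if (!d$form %in% c("linear", "hinge_below", "hinge_above")) {
      stop("configuration error: unknown driver form '", d$form, "'", call. = FALSE)
    }
  }
  structure(list(baseline_yield = baseline_yield,
                 driver_weights = driver_weights,
                 dul_breakpoint = dul_breakpoint, dul_penalty = dul_penalty,
                 county_effect_sd = county_effect_sd, year_trend = year_trend,
                 noise_sd = noise_sd),
            class = "yield_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default drivers: early-season radiation and wind depress yield, warm
# mid-autumn maxima help establishment, late-winter frost (weekly-mean Tmin
# below 0 deg C over weeks 20-23) and spring drought (precipitation below
# 14 mm/week over weeks 30-33) act through deficit hinges.
default_driver_weights <- function() {
  list(
    list(variable = "Wind",          weeks = 9:11,  weight = -0.60, form = "linear"),
    list(variable = "Tmax",          weeks = 7:9,   weight =  0.24, form = "linear"),
    list(variable = "Radiation",     weeks = 6:8,   weight = -0.24, form = "linear"),
    list(variable = "Tmin",          weeks = 20:23, weight =  1.00, form = "hinge_below", threshold = 0),
    list(variable = "Precipitation", weeks = 30:33, weight =  0.30, form = "hinge_below", threshold = 14)
  )
}

#' Query the ground-truth driver feature set
#'
#' Returns the names of the feature columns that carry a nonzero partial
#' effect in the generative yield response: every weekly weather column
#' inside a driver window, plus `"DUL"` when the DUL penalty is active.
#'
#' @param truth A [yield_truth()] object.
#' @return Character vector of feature column names.
#' @export
truth_features <- function(truth) {
  stopifnot(inherits(truth, "yield_truth"))
  cols <- unlist(lapply(truth$driver_weights, function(d) {
    if (d$weight == 0) return(character(0))
    paste0(d$variable, "_", d$weeks)
  }))
  if (truth$dul_penalty != 0) cols <- c(cols, "DUL")
  unique(cols)
}

#' Generator configuration
#'
#' @param n_counties number of counties (default 271)
#' @param years inclusive integer range of panel years (default 1999:2019)
#' @param n_weeks weekly series length, season-relative (default 45)
#' @param weather_params named list (one [weather_var_params()] per entry of
#'   [weather_variables()])
#' @param soil_ranges list of length-2 sampling bounds for LL, DUL, SAT
#'   (cm3/cm3) and BD (g/cm3); ranges must be ordered so every sampled row
#'   satisfies LL < DUL < SAT
#' @param phenology_params list with `mean` and `sd` (day-of-year) for
#'   SowingDOY, FloweringDOY, HarvestDOY
#' @param yield_params a [yield_truth()] object
#' @param seed integer RNG seed
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_counties = 271,
                             years = 1999:2019,
                             n_weeks = 45,
                             weather_params = default_weather_params(),
                             soil_ranges = list(LL = c(0.05, 0.15),
                                                DUL = c(0.18, 0.40),
                                                SAT = c(0.41, 0.55),
                                                BD = c(1.1, 1.7)),
                             phenology_params = list(
                               SowingDOY = list(mean = 288, sd = 7),
                               FloweringDOY = list(mean = 157, sd = 6),
                               HarvestDOY = list(mean = 208, sd = 6)),
                             yield_params = yield_truth(),
                             seed = 1L) {
  if (n_counties < 1) stop("configuration error: n_counties must be >= 1", call. = FALSE)
  if (n_weeks < 1) stop("configuration error: n_weeks must be >= 1", call. = FALSE)
  years <- sort(unique(as.integer(years)))
  miss <- setdiff(weather_variables(), names(weather_params))
  if (length(miss)) {
    stop("configuration error: weather_params missing variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in c("LL", "DUL", "SAT", "BD")) {
    r <- soil_ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) {
      stop("configuration error: soil_ranges$", nm,
           " must be an ordered length-2 range", call. = FALSE)
    }
  }
  if (soil_ranges$DUL[1] <= soil_ranges$LL[2]) {
    stop("configuration error: soil_ranges$DUL lower bound must exceed the ",
         "LL upper bound so that LL < DUL holds for every row", call. = FALSE)
  }
  if (soil_ranges$SAT[1] <= soil_ranges$DUL[2]) {
    stop("configuration error: soil_ranges$SAT lower bound must exceed the ",
         "DUL upper bound so that DUL < SAT holds for every row", call. = FALSE)
  }
  if (soil_ranges$BD[1] <= 0) {
    stop("configuration error: soil_ranges$BD must be positive", call. = FALSE)
  }
  # driver windows must fit into the simulated season
  for (d in yield_params$driver_weights) {
    if (any(d$weeks < 1) || any(d$weeks > n_weeks)) {
      stop("configuration error: driver window for ", d$variable,
           " lies outside [1, ", n_weeks, "]", call. = FALSE)
    }
  }
  structure(list(n_counties = as.integer(n_counties), years = years,
                 n_weeks = as.integer(n_weeks),
                 weather_params = weather_params, soil_ranges = soil_ranges,
                 phenology_params = phenology_params,
                 yield_params = yield_params, seed = as.integer(seed)),
            class = "generator_config")
}

seasonal_curve <- function(p, weeks) {
  p$base + p$amp * cos(2 * pi * (weeks - p$peak_week) / 52)
}

# single driver term on a window mean
driver_term <- function(d, m) {
  switch(d$form %||% "linear",
         linear      = d$weight * m,
         hinge_below = -d$weight * pmax(0, d$threshold - m),
         hinge_above = -d$weight * pmax(0, m - d$threshold),
         stop("configuration error: unknown driver form '", d$form, "'",
              call. = FALSE))
}

#' Ground-truth yield response for a single county-year
#'
#' Deterministic when `noise_draw`, `county_effect` and `year_offset` are
#' zero; see [yield_truth()] for the functional form.
#'
#' @param weather 6 x n_weeks numeric matrix with rownames
#'   [weather_variables()]
#' @param soil named numeric vector with elements LL, DUL, SAT, BD
#' @param phenology named numeric vector (SowingDOY, FloweringDOY,
#'   HarvestDOY); carried for interface symmetry, no default driver uses it
#' @param truth a [yield_truth()] object
#' @param noise_draw residual to add (t/ha), e.g. `rnorm(1, 0, truth$noise_sd)`
#' @param county_effect county-level yield shift (t/ha)
#' @param year_offset years since the panel's first year (drives the trend)
#' @return Yield in t/ha.
#' @export
yield_response <- function(weather, soil, phenology, truth,
                           noise_draw = 0, county_effect = 0, year_offset = 0) {
  stopifnot(inherits(truth, "yield_truth"), is.matrix(weather))
  n_weeks <- ncol(weather)
  y <- truth$baseline_yield
  for (d in truth$driver_weights) {
    if (any(d$weeks < 1) || any(d$weeks > n_weeks)) {
      stop("configuration error: driver window for ", d$variable,
           " lies outside [1, ", n_weeks, "]", call. = FALSE)
    }
    m <- mean(weather[d$variable, d$weeks])
    y <- y + driver_term(d, m)
  }
  y <- y - truth$dul_penalty * max(0, truth$dul_breakpoint - soil[["DUL"]])
  y + county_effect + truth$year_trend * year_offset + noise_draw
}

# AR(1) matrix simulation: one series per row, stationary start.
simulate_ar1 <- function(n_rows, n_weeks, phi, sd_inn) {
  e <- matrix(0, n_rows, n_weeks)
  if (sd_inn == 0) return(e)
  e[, 1] <- rnorm(n_rows, 0, sd_inn / sqrt(1 - phi^2))
  if (n_weeks > 1) {
    for (w in 2:n_weeks) e[, w] <- phi * e[, w - 1] + rnorm(n_rows, 0, sd_inn)
  }
  e
}

#' Generate a synthetic county-year panel
#'
#' Weather is seasonal mean + county effect + year anomaly + AR(1) weekly
#' noise; soil is sampled once per county and held constant across years;
#' phenology dates are jittered per county-year; yield follows the
#' ground-truth response of [yield_truth()]. Regeneration with the same
#' config (including seed) is bit-identical.
#'
#' @param config a [generator_config()]
#' @return An object of class `panel_table`: a list with `data` (one row per
#'   county-year; weekly columns named `<Variable>_<week>`), `n_weeks`,
#'   `truth`, and the generating `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nc <- config$n_counties
  yrs <- config$years
  ny <- length(yrs)
  L <- config$n_weeks
  n <- nc * ny
  county_id <- sprintf("C%04d", seq_len(nc))

  # static soil, one draw per county
  sr <- config$soil_ranges
  soil <- data.frame(
    LL  = runif(nc, sr$LL[1], sr$LL[2]),
    DUL = runif(nc, sr$DUL[1], sr$DUL[2]),
    SAT = runif(nc, sr$SAT[1], sr$SAT[2]),
    BD  = runif(nc, sr$BD[1], sr$BD[2])
  )

  county_yield_effect <- rnorm(nc, 0, config$yield_params$county_effect_sd)

  rows <- data.frame(
    county_id = rep(county_id, each = ny),
    year = rep(yrs, times = nc),
    stringsAsFactors = FALSE
  )
  ci <- rep(seq_len(nc), each = ny)   # county index per row
  yi <- rep(seq_len(ny), times = nc)  # year index per row

  # phenology: per county-year Gaussian jitter around the calendar means
  php <- config$phenology_params
  phen <- sapply(c("SowingDOY", "FloweringDOY", "HarvestDOY"), function(nm) {
    v <- round(rnorm(n, php[[nm]]$mean, php[[nm]]$sd))
    pmin(pmax(v, 1), 366)
  })

  # weather: per variable, a (row x week) matrix
  weather <- vector("list", length(weather_variables()))
  names(weather) <- weather_variables()
  for (v in weather_variables()) {
    p <- config$weather_params[[v]]
    a_c <- rnorm(nc, 0, p$county_sd)
    b_y <- rnorm(ny, 0, p$year_sd)
    e <- simulate_ar1(n, L, p$ar1, p$innovation_sd)
    m <- matrix(seasonal_curve(p, seq_len(L)), n, L, byrow = TRUE) +
      a_c[ci] + b_y[yi] + e
    if (!is.na(p$lower)) m <- pmax(m, p$lower)
    if (!is.na(p$upper)) m <- pmin(m, p$upper)
    colnames(m) <- paste0(v, "_", seq_len(L))
    weather[[v]] <- m
  }

  # ground-truth yield, vectorised over rows
  truth <- config$yield_params
  y <- rep(truth$baseline_yield, n)
  for (d in truth$driver_weights) {
    wm <- weather[[d$variable]][, d$weeks, drop = FALSE]
    y <- y + driver_term(d, rowMeans(wm))
  }
  y <- y - truth$dul_penalty * pmax(0, truth$dul_breakpoint - soil$DUL[ci])
  y <- y + county_yield_effect[ci] +
    truth$year_trend * (rows$year - min(yrs)) +
    rnorm(n, 0, truth$noise_sd)

  dat <- cbind(rows, do.call(cbind, unname(lapply(weather, as.data.frame))),
               as.data.frame(phen), soil[ci, , drop = FALSE],
               Yield = y)
  rownames(dat) <- NULL

  structure(list(data = dat, n_weeks = L, truth = truth, config = config),
            class = "panel_table")
}

#' @exportS3Method base::print
print.panel_table <- function(x, ...) {
  cat("panel_table:", nrow(x$data), "county-year rows,",
      x$n_weeks, "weeks x 6 weather variables\n")
  invisible(x)
}

#' Write a panel (and its driver manifest) to disk
#'
#' The panel goes to CSV (one row per county-year, `<Variable>_<week>`
#' weekly columns, then `SowingDOY, FloweringDOY, HarvestDOY, LL, DUL, SAT,
#' BD, Yield`); the ground-truth driver manifest goes to a JSON file next to
#' it (same path with extension `.truth.json`) unless `manifest = FALSE`.
#'
#' @param panel a `panel_table`
#' @param path output CSV path
#' @param manifest also write the driver manifest JSON?
#' @return Invisibly, the CSV path.
#' @export
write_panel <- function(panel, path, manifest = TRUE) {
  stopifnot(inherits(panel, "panel_table"))
  utils::write.csv(panel$data, path, row.names = FALSE)
  if (manifest) {
    mpath <- sub("\\.csv$", "", path)
    mpath <- paste0(mpath, ".truth.json")
    tr <- panel$truth
    jsonlite::write_json(
      list(baseline_yield = tr$baseline_yield,
           dul_breakpoint = tr$dul_breakpoint,
           dul_penalty = tr$dul_penalty,
           county_effect_sd = tr$county_effect_sd,
           year_trend = tr$year_trend,
           noise_sd = tr$noise_sd,
           drivers = lapply(tr$driver_weights, function(d) {
             list(variable = d$variable, weeks = d$weeks, weight = d$weight,
                  form = d$form %||% "linear",
                  threshold = d$threshold %||% NA)
           }),
           driver_features = truth_features(tr)),
      mpath, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a county-year panel from CSV
#'
#' Adapter for externally prepared panels following the documented schema
#' (see [write_panel()]): `county_id`, `year`, six blocks of weekly columns
#' `<Variable>_<week>`, the seven static columns, and optionally `Yield`.
#'
#' @param path CSV path
#' @return A `panel_table` (with `truth = NULL`).
#' @export
read_panel <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  wk <- grep(paste0("^(", paste(weather_variables(), collapse = "|"), ")_\\d+$"),
             names(dat), value = TRUE)
  if (!length(wk)) stop("no weekly weather columns found in ", path, call. = FALSE)
  n_weeks <- max(as.integer(sub("^.*_", "", wk)))
  structure(list(data = dat, n_weeks = n_weeks, truth = NULL, config = NULL),
            class = "panel_table")
}
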
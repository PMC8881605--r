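# Shared fixtures, generated in code at test time.

# small panel: full 45-week feature layout but few rows
small_panel <- function(n_counties = 8, years = 2004:2009, seed = 42, ...) {
  generate_panel(generator_config(n_counties = n_counties, years = years,
                                  seed = seed, ...))
}

small_split <- function(test_year = 2009, ...) {
  tab <- assemble_feature_table(small_panel(...))
  sp <- temporal_split(tab, test_year)
  norm <- fit_normalizer(sp$train)
  list(train = apply_normalizer(sp$train, norm),
       test = apply_normalizer(sp$test, norm),
       norm = norm, table = tab)
}

# deterministic single-row inputs for yield_response
unit_weather <- function(n_weeks = 45, value = 5) {
  m <- matrix(value, 6, n_weeks, dimnames = list(weather_variables(), NULL))
  m
}

unit_soil <- function(DUL = 0.30) {
  c(LL = 0.10, DUL = DUL, SAT = 0.45, BD = 1.4)
}

unit_phen <- c(SowingDOY = 288, FloweringDOY = 157, HarvestDOY = 208)

rmse_of <- function(fit, x, y) sqrt(mean((predict(fit, x) - y)^2))
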
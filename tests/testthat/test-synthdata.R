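# Synthetic county-year panel generator.

test_that("generate_panel produces the expected row grid and is deterministic", {
  cfg <- generator_config(n_counties = 4, years = 2001:2003, seed = 7)
  p1 <- generate_panel(cfg)
  expect_equal(nrow(p1$data), 12)  # 4 counties x 3 years
  p2 <- generate_panel(cfg)
  expect_identical(p1$data, p2$data)
  # different seed changes the draw
  p3 <- generate_panel(generator_config(n_counties = 4, years = 2001:2003,
                                        seed = 8))
  expect_false(identical(p1$data, p3$data))
})

test_that("every generated row satisfies the soil, DOY and weather invariants", {
  p <- small_panel(n_counties = 12, years = 2000:2006, seed = 3)
  d <- p$data
  expect_true(all(d$LL < d$DUL & d$DUL < d$SAT))
  expect_true(all(d$BD > 0))
  for (col in c("SowingDOY", "FloweringDOY", "HarvestDOY")) {
    expect_true(all(d[[col]] >= 1 & d[[col]] <= 366))
  }
  wk <- as.matrix(d[, yieldcnn:::weather_column_names(p$n_weeks)])
  expect_equal(ncol(wk), 6 * p$n_weeks)
  expect_true(all(is.finite(wk)))
  # soil static per county across years
  per_county <- tapply(d$DUL, d$county_id, function(v) length(unique(v)))
  expect_true(all(per_county == 1))
})

test_that("invalid configurations fail with errors naming the offending field", {
  expect_error(generator_config(soil_ranges = list(LL = c(0.05, 0.25),
                                                   DUL = c(0.18, 0.40),
                                                   SAT = c(0.41, 0.55),
                                                   BD = c(1.1, 1.7))),
               "DUL")
  expect_error(weather_var_params(1, 1, 1, 1, 1, ar1 = 1, innovation_sd = 1),
               "ar1")
  tr <- yield_truth(driver_weights = list(
    list(variable = "Wind", weeks = 50:52, weight = 1, form = "linear")))
  expect_error(generator_config(n_weeks = 45, yield_params = tr),
               "driver window")
  expect_error(yield_truth(noise_sd = -1), "noise_sd")
  expect_error(generator_config(n_weeks = 0), "n_weeks")
})

test_that("yield_response is deterministic and penalises DUL below the breakpoint", {
  tr <- yield_truth()
  w <- unit_weather()
  y1 <- yield_response(w, unit_soil(DUL = 0.30), unit_phen, tr)
  y2 <- yield_response(w, unit_soil(DUL = 0.30), unit_phen, tr)
  expect_identical(y1, y2)
  # DUL below the 0.27 cm3/cm3 breakpoint strictly lowers yield
  y_low <- yield_response(w, unit_soil(DUL = 0.22), unit_phen, tr)
  expect_lt(y_low, y1)
  # above the breakpoint the penalty vanishes
  y_hi <- yield_response(w, unit_soil(DUL = 0.35), unit_phen, tr)
  expect_equal(y_hi, y1)
})

test_that("Monte-Carlo mean of the noisy response matches the analytic expectation", {
  # the only stochastic term passed in is additive Gaussian noise, so the
  # expectation equals the deterministic response; 10,000 draws, 3 SE band
  tr <- yield_truth(noise_sd = 0.4)
  w <- unit_weather()
  s <- unit_soil(0.24)
  det <- yield_response(w, s, unit_phen, tr)
  set.seed(99)
  draws <- vapply(rnorm(10000, 0, tr$noise_sd), function(e) {
    yield_response(w, s, unit_phen, tr, noise_draw = e)
  }, numeric(1))
  se <- tr$noise_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - det), 3 * se)
})

test_that("features outside the driver set have zero partial effect (finite differences)", {
  tr <- yield_truth(noise_sd = 0)
  w <- unit_weather()
  s <- unit_soil(0.24)
  base <- yield_response(w, s, unit_phen, tr)
  drivers <- truth_features(tr)
  for (v in weather_variables()) {
    for (wk in c(1, 15, 28, 45)) {
      w2 <- w
      w2[v, wk] <- w2[v, wk] + 1
      dy <- yield_response(w2, s, unit_phen, tr) - base
      if (paste0(v, "_", wk) %in% drivers) {
        expect_gt(abs(dy), 0)
      } else {
        expect_equal(dy, 0)
      }
    }
  }
  # a true weekly driver inside its window moves the response
  w2 <- w; w2["Wind", 10] <- w2["Wind", 10] + 1
  expect_false(yield_response(w2, s, unit_phen, tr) == base)
})

test_that("AR(1) weekly noise has the configured lag-1 autocorrelation", {
  # Tmin is untruncated; remove the seasonal curve and the per-row mean
  # (county + year effects), then pool lag-1 pairs; >= 1e4 samples
  phi <- 0.5
  p <- generate_panel(generator_config(n_counties = 60, years = 2000:2009,
                                       seed = 5))
  d <- p$data
  wk <- as.matrix(d[, paste0("Tmin_", seq_len(p$n_weeks))])
  pars <- p$config$weather_params$Tmin
  curve <- yieldcnn:::seasonal_curve(pars, seq_len(p$n_weeks))
  e <- sweep(wk, 2, curve)
  e <- e - rowMeans(e)
  x <- as.vector(t(e[, -p$n_weeks]))
  y <- as.vector(t(e[, -1]))
  expect_gt(length(x), 1e4)
  expect_lt(abs(cor(x, y) - pars$ar1), 0.1)
})

test_that("truth manifest records and queries the nonzero driver set", {
  tr <- yield_truth()
  drv <- truth_features(tr)
  expect_true("DUL" %in% drv)
  expect_true(all(paste0("Wind_", 9:11) %in% drv))
  expect_true(all(paste0("Tmin_", 20:23) %in% drv))
  # zero-weight drivers and disabled DUL penalty drop out
  tr0 <- yield_truth(driver_weights = list(
    list(variable = "Wind", weeks = 1:2, weight = 0, form = "linear"),
    list(variable = "Tmax", weeks = 3:4, weight = 1, form = "linear")),
    dul_penalty = 0)
  expect_identical(truth_features(tr0), paste0("Tmax_", 3:4))
})

test_that("panel CSV round-trips and the driver manifest is written", {
  p <- small_panel(n_counties = 3, years = 2001:2002)
  path <- file.path(tempdir(), "panel_rt.csv")
  write_panel(p, path)
  expect_true(file.exists(sub("\\.csv$", ".truth.json", path)))
  man <- jsonlite::read_json(sub("\\.csv$", ".truth.json", path),
                             simplifyVector = TRUE)
  expect_setequal(man$driver_features, truth_features(p$truth))
  p2 <- read_panel(path)
  expect_equal(p2$n_weeks, p$n_weeks)
  expect_equal(p2$data$Yield, p$data$Yield, tolerance = 1e-12)
  unlink(c(path, sub("\\.csv$", ".truth.json", path)))
})
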
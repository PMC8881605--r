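# Kernel SHAP, global importance, force data, profiles, ablation.

# helper to fabricate a shap_matrix with known contributions
fake_shap <- function(contrib, base = 5) {
  structure(list(contributions = contrib, base_value = base,
                 prediction = base + rowSums(contrib),
                 budget = 0, n_background = 0),
            class = "shap_matrix")
}

test_that("exact enumeration recovers the additive closed form", {
  # f(x) = 2 x1 + 3, independent background: phi_1 = 2 (x1 - mean bg x1),
  # all other features are null players
  set.seed(1)
  M <- 8
  bg <- matrix(rnorm(40 * M), 40, dimnames = list(NULL, paste0("f", 1:M)))
  X <- matrix(rnorm(6 * M), 6, dimnames = list(NULL, paste0("f", 1:M)))
  f <- function(x) 2 * x[, 1] + 3
  sh <- shap_values(f, bg, X, budget = 2^M, seed = 1, ridge = 0)
  expect_equal(sh$base_value, mean(2 * bg[, 1] + 3))
  expect_equal(sh$contributions[, 1], 2 * (X[, 1] - mean(bg[, 1])),
               tolerance = 1e-8)
  expect_equal(max(abs(sh$contributions[, -1])), 0, tolerance = 1e-8)
  # local accuracy is exact
  expect_equal(rowSums(sh$contributions) + sh$base_value, sh$prediction,
               tolerance = 1e-10)
})

test_that("sampled coalitions keep local accuracy and near-closed-form additivity", {
  set.seed(2)
  M <- 40  # too wide to enumerate at this budget
  bg <- matrix(rnorm(30 * M), 30, dimnames = list(NULL, paste0("f", 1:M)))
  X <- matrix(rnorm(5 * M, sd = 2), 5, dimnames = list(NULL, paste0("f", 1:M)))
  beta <- c(2, -1.5, rep(0, M - 2))
  f <- function(x) as.numeric(x %*% beta) + 1
  sh <- shap_values(f, bg, X, budget = 2 * M + 48, seed = 3)
  expect_equal(rowSums(sh$contributions) + sh$base_value, sh$prediction,
               tolerance = 1e-10)
  truth1 <- 2 * (X[, 1] - mean(bg[, 1]))
  expect_equal(sh$contributions[, 1], truth1,
               tolerance = 0.05 * max(abs(truth1)))
  expect_error(shap_values(f, bg, X[, 1:10]), "schema mismatch")
})

test_that("global importance is mean |contribution| with correlation signs", {
  set.seed(4)
  contrib <- cbind(a = rnorm(30), b = rep(0, 30), c = rnorm(30, 0, 3))
  vals <- cbind(a = contrib[, "a"] * 2, b = rnorm(30),
                c = -contrib[, "c"])
  sh <- fake_shap(contrib)
  imp <- global_importance(sh, vals)
  # brute-force recomputation
  expect_equal(imp$importance,
               unname(apply(abs(contrib), 2, function(cc) sum(cc) / length(cc))))
  expect_equal(imp$rank, rank(-imp$importance, ties.method = "first"))
  expect_equal(imp$sign[imp$feature == "a"], 1)
  expect_equal(imp$sign[imp$feature == "b"], 0)
  expect_equal(imp$sign[imp$feature == "c"], -1)
  expect_equal(imp$feature[imp$rank == 1], "c")
  expect_setequal(imp$rank, 1:3)

  zero <- fake_shap(contrib * 0)
  expect_true(all(global_importance(zero, vals)$importance == 0))
  expect_error(global_importance(fake_shap(contrib[0, , drop = FALSE]),
                                 vals[0, , drop = FALSE]), "empty")
  expect_equal(nrow(top_features(imp, 2)), 2)
})

test_that("force data selects min/median/max by actual yield with the lower-middle rule", {
  contrib <- matrix(rnorm(4 * 3), 4, dimnames = list(NULL, c("a", "b", "c")))
  sh <- fake_shap(contrib)
  yields <- c(7.2, 5.1, 6.0, 6.4)
  expect_equal(force_data(sh, yields, "min")$instance, 2)
  expect_equal(force_data(sh, yields, "max")$instance, 1)
  # even count: lower of the two middle yields (6.0 over 6.4)
  expect_equal(force_data(sh, yields, "median")$instance, 3)
  fd <- force_data(sh, yields, "max")
  expect_equal(fd$base_value + sum(fd$contributions$contribution),
               fd$output_value, tolerance = 1e-12)
  expect_false(is.unsorted(rev(abs(fd$contributions$contribution))))
  # single instance: min = median = max
  sh1 <- fake_shap(contrib[1, , drop = FALSE])
  expect_equal(force_data(sh1, 5, "min")$instance,
               force_data(sh1, 5, "median")$instance)
  expect_error(force_data(sh, numeric(0)), "empty")
})

test_that("weekly weather profile aggregates by variable and normalises to 100", {
  cols <- c(yieldcnn:::weather_column_names(3), static_columns())
  n <- length(cols)
  uni <- matrix(1, 4, n, dimnames = list(NULL, cols))
  prof <- weekly_weather_profile(fake_shap(uni))
  expect_equal(sum(prof$totals), 100)
  expect_equal(unname(prof$totals), rep(100 / 6, 6))
  expect_equal(nrow(prof$grid), 18)

  solo <- matrix(0, 4, n, dimnames = list(NULL, cols))
  solo[, "Wind_2"] <- 2
  prof2 <- weekly_weather_profile(fake_shap(solo))
  expect_equal(unname(prof2$totals["Wind"]), 100)
  # brute-force grouped totals agree exactly
  set.seed(5)
  rnd <- matrix(rnorm(4 * n), 4, dimnames = list(NULL, cols))
  prof3 <- weekly_weather_profile(fake_shap(rnd))
  brute <- sapply(weather_variables(), function(v) {
    sum(colMeans(abs(rnd[, grep(paste0("^", v, "_"), cols), drop = FALSE])))
  })
  expect_equal(unname(prof3$totals[names(brute)]),
               unname(100 * brute / sum(brute)))

  nowx <- matrix(1, 2, 7, dimnames = list(NULL, static_columns()))
  expect_error(weekly_weather_profile(fake_shap(nowx)), "no weather columns")
})

test_that("ablation subsets follow the ceiling rule and the weather-only count", {
  tab <- assemble_feature_table(small_panel(n_counties = 6, years = 2004:2007,
                                            seed = 9))
  # fabricated importance: rank by column position
  imp <- data.frame(feature = colnames(tab$x),
                    importance = rev(seq_len(ncol(tab$x))),
                    sign = 1, rank = seq_len(ncol(tab$x)))
  class(imp) <- c("importance_table", "data.frame")
  suppressWarnings(
    res <- ablation_retrain(baseline_spec("lasso", seed = 1), tab, imp,
                            test_years = 2007)
  )
  nf <- unique(res[, c("subset", "n_features")])
  expect_equal(nf$n_features[nf$subset == "full"], 277)
  expect_equal(nf$n_features[nf$subset == "top_75pct"], 208)  # ceiling(207.75)
  expect_equal(nf$n_features[nf$subset == "top_50pct"], 139)  # ceiling(138.5)
  expect_equal(nf$n_features[nf$subset == "weather_only"], 270)  # 6 x 45
  expect_true(all(is.finite(res$rmse)))
  expect_error(ablation_retrain(baseline_spec("lasso"), tab, imp,
                                test_years = 2007, fractions = 1.2),
               "fractions")
})
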
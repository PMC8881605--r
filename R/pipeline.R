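# Config-driven end-to-end orchestration and the command-line interface.

#' Build a validated experiment configuration
#'
#' Master-seed discipline: every stochastic stage derives its own seed
#' deterministically from `seed` (small fixed offsets), so one integer
#' reproduces the whole run.
#'
#' @param out_dir artifact output directory (required)
#' @param seed master seed (required)
#' @param generator list of arguments for [generator_config()]
#' @param arch list of arguments for [cnn_arch_config()]
#' @param train list of arguments for [train_config()]
#' @param baselines character vector of baseline names to benchmark
#' @param tune logical: run the CV hyperparameter search per baseline?
#' @param search list of arguments for [search_spec()] (minus `space`)
#' @param test_years hold-out years (default: last three panel years)
#' @param explain list: `background_n`, `instance_n`, `budget` for SHAP
#' @param ablation_fractions fractions for [ablation_retrain()]
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(out_dir, seed,
                              generator = list(),
                              arch = list(),
                              train = list(),
                              baselines = c("knn", "random_forest", "xgboost",
                                            "lasso", "ridge", "regression_tree",
                                            "svr", "dnn"),
                              tune = FALSE,
                              search = list(n_iter = 10L, k_folds = 3L,
                                            strategy = "randomized"),
                              test_years = NULL,
                              explain = list(background_n = 100L,
                                             instance_n = 200L, budget = NULL),
                              ablation_fractions = c(1, 0.75, 0.5)) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop("validation error: required field 'out_dir' is missing", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("validation error: required field 'seed' is missing", call. = FALSE)
  }
  seed <- as.integer(seed)
  gen <- do.call(generator_config,
                 c(generator[setdiff(names(generator), "seed")],
                   list(seed = seed)))
  arch_cfg <- do.call(cnn_arch_config, arch)
  train_cfg <- do.call(train_config,
                       c(train[setdiff(names(train), "seed")],
                         list(seed = seed + 1L)))
  bad <- setdiff(baselines, BASELINE_NAMES)
  if (length(bad)) {
    stop("validation error: unknown baseline(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(test_years)) {
    ny <- length(gen$years)
    test_years <- gen$years[max(1, ny - 2):ny]
  }
  if (!all(test_years %in% gen$years) || min(test_years) <= min(gen$years)) {
    stop("validation error: every test year needs preceding training years ",
         "inside the panel range", call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = seed, generator = gen,
                 arch = arch_cfg, train = train_cfg, baselines = baselines,
                 tune = isTRUE(tune), search = search,
                 test_years = as.integer(test_years), explain = explain,
                 ablation_fractions = ablation_fractions),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite)
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("validation error: unknown config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$generator$years)) {
    raw$generator$years <- seq(min(raw$generator$years), max(raw$generator$years))
  }
  do.call(experiment_config, raw)
}

#' Run a full experiment and write its artifact directory
#'
#' Stages: synthetic panel generation, feature assembly, the multi-model
#' year-wise benchmark, Kernel SHAP explanation of the trained CNN
#' (global importance, per-instance force data, weekly weather profile),
#' and the Shapley-ranked feature-selection ablation. Artifacts (all CSV,
#' UTF-8, header row): `panel.csv` (+ `panel.truth.json`), `features.csv`,
#' `benchmark.csv`, `importance.csv`, `force.csv`, `weekly_profile.csv`,
#' `ablation.csv`, plus `run_log.json` recording every default that filled
#' an unspecified parameter.
#'
#' @param config an `experiment_config`, or a path to a YAML/JSON config
#' @param stages subset of stages to run (artifact dependencies are
#'   recomputed as needed)
#' @return Invisibly, the artifact directory path.
#' @export
run_experiment <- function(config,
                           stages = c("generate", "features", "benchmark",
                                      "explain", "ablate")) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(config$out_dir, f)
  log <- list(seed = config$seed,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("yieldcnn")),
              defaults = list(
                arch = unclass(config$arch),
                train = unclass(config$train),
                explain = config$explain,
                search = config$search,
                baseline_hyper = stats::setNames(
                  lapply(config$baselines, default_hyper), config$baselines)))

  panel <- generate_panel(config$generator)
  if ("generate" %in% stages) write_panel(panel, op("panel.csv"))

  table <- assemble_feature_table(panel)
  if ("features" %in% stages) write_feature_table(table, op("features.csv"))

  cnn_sp <- cnn_spec(config$arch, config$train, n_weeks = config$generator$n_weeks,
                     seed = config$seed + 1L)

  if ("benchmark" %in% stages) {
    models <- stats::setNames(
      lapply(seq_along(config$baselines), function(i) {
        baseline_spec(config$baselines[i], seed = config$seed + 10L + i)
      }), config$baselines)
    models$cnn <- cnn_sp
    tune <- NULL
    if (config$tune) {
      tune <- stats::setNames(lapply(config$baselines, function(nm) {
        do.call(search_spec, c(list(space = default_search_space(nm)),
                               config$search,
                               list(seed = config$seed + 5L)))
      }), config$baselines)
    }
    bench <- benchmark(models, table, config$test_years, tune = tune,
                       keep_predictions = TRUE)
    utils::write.csv(benchmark_wide(bench), op("benchmark.csv"), row.names = FALSE)
    utils::write.csv(bench$predictions, op("predictions.csv"), row.names = FALSE)
  }

  imp <- NULL
  if (any(c("explain", "ablate") %in% stages)) {
    ty <- max(config$test_years)
    sp <- temporal_split(table, ty)
    norm <- fit_normalizer(sp$train)
    trn <- apply_normalizer(sp$train, norm)
    ten <- apply_normalizer(sp$test, norm)
    model <- build_cnn(config$arch, n_weeks = config$generator$n_weeks,
                       n_static = length(static_columns()),
                       seed = config$seed + 1L)
    model <- train_cnn(model, trn, config$train)

    ex <- config$explain
    set.seed(config$seed + 2L)
    bg <- subset_rows(trn, sample.int(nrow(trn$x), min(ex$background_n, nrow(trn$x))))
    inst <- subset_rows(ten, sample.int(nrow(ten$x), min(ex$instance_n, nrow(ten$x))))
    shap <- shap_values(model_predict_fn(model), bg, inst,
                        budget = ex$budget, seed = config$seed + 3L)
    imp <- global_importance(shap, inst)

    if ("explain" %in% stages) {
      utils::write.csv(imp[order(imp$rank), ], op("importance.csv"),
                       row.names = FALSE)
      fd <- do.call(rbind, lapply(c("min", "median", "max"), function(s) {
        f <- force_data(shap, inst$y, s)
        cbind(data.frame(selector = s, instance = f$instance,
                         actual = f$actual, base_value = f$base_value,
                         output_value = f$output_value),
              f$contributions)
      }))
      utils::write.csv(fd, op("force.csv"), row.names = FALSE)
      prof <- weekly_weather_profile(shap)
      utils::write.csv(prof$grid, op("weekly_profile.csv"), row.names = FALSE)
      log$weather_totals <- as.list(prof$totals)
    }

    if ("ablate" %in% stages) {
      abl <- ablation_retrain(cnn_sp, table, imp, config$test_years,
                              fractions = config$ablation_fractions)
      utils::write.csv(abl, op("ablation.csv"), row.names = FALSE)
    }
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, op("run_log.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `features`, `train-cnn`, `benchmark`, `explain`,
#' `ablate`, `run-all`. Invoke via the installed script:
#' `Rscript -e 'yieldcnn::run_cli()' <subcommand> --config cfg.yaml`
#' or `Rscript $(Rscript -e 'cat(system.file("cli.R", package="yieldcnn"))') ...`
#'
#' @param args character vector of CLI arguments (default: `commandArgs(TRUE)`)
#' @return Invisibly, the artifact directory (where applicable).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: <generate|features|train-cnn|benchmark|explain|ablate|run-all>",
    "[--config PATH] [--seed INT] [--out DIR] [--test-years Y1,Y2,...]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  cmd <- args[1]
  rest <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL, test_years = NULL)
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!key %in% c("--config", "--seed", "--out", "--test-years")) {
      stop("unknown flag ", key, "\n", usage, call. = FALSE)
    }
    if (i == length(rest)) stop("missing value for ", key, call. = FALSE)
    val <- rest[i + 1]
    switch(key,
           "--config" = opt$config <- val,
           "--seed" = opt$seed <- as.integer(val),
           "--out" = opt$out <- val,
           "--test-years" = opt$test_years <- as.integer(strsplit(val, ",")[[1]]))
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_experiment_config(opt$config)
         else experiment_config(out_dir = opt$out %||% "yieldcnn_run",
                                seed = opt$seed %||% 1L)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$test_years)) cfg$test_years <- opt$test_years

  stages <- switch(cmd,
                   "generate" = "generate",
                   "features" = c("generate", "features"),
                   "train-cnn" = "explain",   # trains the CNN en route
                   "benchmark" = "benchmark",
                   "explain" = "explain",
                   "ablate" = "ablate",
                   "run-all" = c("generate", "features", "benchmark",
                                 "explain", "ablate"),
                   stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  run_experiment(cfg, stages = stages)
}
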
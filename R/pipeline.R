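pipeline_subcommands <- function() {
  c("simulate", "windows", "fit", "cv", "sweep-w", "sweep-h", "check",
    "importance")
}

# Fill a run configuration with defaults and validate it.
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config[["seed"]] <- as.integer(config[["seed"]] %||% 1L)
  config[["w"]] <- config[["w"]] %||% 4
  config[["h"]] <- config[["h"]] %||% 1
  config[["models"]] <- config[["models"]] %||% c("pooled_mean", "last_observed",
                                        "pooled_ridge", "hier_linear")
  config[["model"]] <- config[["model"]] %||% "hier_linear"
  config[["mcmc"]] <- config[["mcmc"]] %||% list()
  config[["mcmc"]] <- list(chains = config[["mcmc"]][["chains"]] %||% 4,
                      iterations = config[["mcmc"]][["iterations"]] %||% 5000,
                      warmup_fraction = config[["mcmc"]][["warmup_fraction"]] %||% 0.5)
  config[["scheme"]] <- config[["scheme"]] %||% list()
  config[["scheme"]] <- list(name = config[["scheme"]][["name"]] %||% "leave_all_out",
                        T = config[["scheme"]][["T"]] %||% 24,
                        partition_length = config[["scheme"]][["partition_length"]] %||% 7,
                        train_period = config[["scheme"]][["train_period"]] %||% 14,
                        test_period = config[["scheme"]][["test_period"]] %||% 154)
  config[["paths"]] <- config[["paths"]] %||% list()
  if (is.null(config[["paths"]][["output_dir"]]))
    stop("invalid config: missing field 'paths$output_dir'", call. = FALSE)
  config
}

pipeline_windows <- function(config) {
  if (is.null(config[["paths"]][["input"]]))
    stop("invalid config: missing field 'paths$input'", call. = FALSE)
  if (!file.exists(config[["paths"]][["input"]]))
    stop(sprintf("input file not found: %s", config[["paths"]][["input"]]),
         call. = FALSE)
  raw <- read_selfassessment_csv(config[["paths"]][["input"]])
  build_windows(raw, w = config[["w"]], h = config[["h"]])
}

pipeline_plan <- function(ds, config) {
  sc <- config[["scheme"]]
  if (sc$name == "leave_all_out")
    make_leave_all_out_splits(ds, T = sc$T,
                              partition_length = sc$partition_length)
  else if (sc$name == "leave_one_out")
    make_leave_one_out_splits(ds, train_period = sc$train_period,
                              test_period = sc$test_period)
  else stop(sprintf("invalid config: unknown scheme '%s'", sc$name),
            call. = FALSE)
}

pipeline_mcmc <- function(config) {
  mcmc_config(chains = config[["mcmc"]][["chains"]],
              iterations = config[["mcmc"]][["iterations"]],
              warmup_fraction = config[["mcmc"]][["warmup_fraction"]],
              seed = config[["seed"]] + 1L)
}

pipeline_model_specs <- function(config) {
  mcmc <- pipeline_mcmc(config)
  stats::setNames(lapply(config[["models"]], function(k) {
    if (k %in% c("hier_linear", "hier_ordinal")) list(kind = k, mcmc = mcmc)
    else list(kind = k)
  }), config[["models"]])
}

#' Run one pipeline stage end-to-end from a configuration
#'
#' Subcommands: \code{simulate} (write a synthetic cohort CSV),
#' \code{windows} (preprocess and window an input CSV), \code{fit} (fit one
#' model and serialize its posterior), \code{cv} (run a cross-validation
#' scheme and write the result tables), \code{sweep-w} / \code{sweep-h}
#' (window-size and horizon sweeps), \code{check} (posterior-predictive
#' tail report), \code{importance} (individual-weight |t| table). Every
#' invocation writes the exact resolved configuration (including the seed)
#' next to its artifacts, so any output is reproducible from its stored
#' config. The single seed fans out deterministically to the generator and
#' sampler seeds.
#'
#' @param subcommand One of \code{pipeline_subcommands()}.
#' @param config A named list or path to a JSON file. Recognised fields:
#'   \code{paths} (\code{input}, \code{output_dir}), \code{w}, \code{h},
#'   \code{h_range} / \code{w_range}, \code{scheme} (\code{name} plus its
#'   parameters), \code{models}, \code{model}, \code{mcmc}
#'   (\code{chains}, \code{iterations}, \code{warmup_fraction}),
#'   \code{population} (generator settings), \code{seed}.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(subcommand, config) {
  if (!subcommand %in% pipeline_subcommands())
    stop(sprintf("unknown subcommand '%s' (expected one of: %s)", subcommand,
                 paste(pipeline_subcommands(), collapse = ", ")),
         call. = FALSE)
  config <- resolve_config(config)
  out_dir <- config[["paths"]][["output_dir"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  if (subcommand == "simulate") {
    pop <- config[["population"]] %||% list()
    pop$seed <- config[["seed"]]
    cfg <- do.call(population_config, pop)
    data <- generate_population(cfg)
    path <- file.path(out_dir, "dataset.csv")
    write_selfassessment_csv(data, path)
    summ <- summarize_population(data)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- list(dataset = path,
                      summary = file.path(out_dir, "summary.json"))
  } else if (subcommand == "windows") {
    ds <- pipeline_windows(config)
    path <- file.path(out_dir, "windows.csv")
    write_windows_csv(ds, path)
    artifacts <- list(windows = path)
  } else if (subcommand == "fit") {
    ds <- pipeline_windows(config)
    mcmc <- pipeline_mcmc(config)
    fit <- if (config[["model"]] == "hier_ordinal")
      fit_hier_ordinal(ds, mcmc = mcmc)
    else fit_hier_linear(ds, mcmc = mcmc)
    pdir <- file.path(out_dir, "posterior")
    write_posterior(fit, pdir)
    artifacts <- list(posterior = pdir)
  } else if (subcommand == "cv") {
    ds <- pipeline_windows(config)
    plan <- pipeline_plan(ds, config)
    cv <- run_cv(pipeline_model_specs(config), ds, plan,
                 seed = config[["seed"]] + 2L)
    utils::write.csv(cv$metrics, file.path(out_dir, "cv_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$predictions, file.path(out_dir, "cv_predictions.csv"),
                     row.names = FALSE)
    audit <- lapply(plan$folds, function(f) list(
      n_train = length(f$train), n_test = length(f$test),
      test_patients = unique(ds$patient_id[f$test]),
      test_dates = range(format(ds$target_date[f$test]))))
    jsonlite::write_json(audit, file.path(out_dir, "folds.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- list(metrics = file.path(out_dir, "cv_metrics.csv"),
                      predictions = file.path(out_dir, "cv_predictions.csv"),
                      folds = file.path(out_dir, "folds.json"))
  } else if (subcommand %in% c("sweep-w", "sweep-h")) {
    if (is.null(config[["paths"]][["input"]]))
      stop("invalid config: missing field 'paths$input'", call. = FALSE)
    raw <- read_selfassessment_csv(config[["paths"]][["input"]])
    specs <- pipeline_model_specs(config)
    sw <- if (subcommand == "sweep-w")
      window_size_sweep(raw, w_range = config[["w_range"]] %||% 1:7,
                        h = config[["h"]], models = specs,
                        scheme = config[["scheme"]][["name"]], T = config[["scheme"]][["T"]],
                        partition_length = config[["scheme"]][["partition_length"]],
                        train_period = config[["scheme"]][["train_period"]],
                        test_period = config[["scheme"]][["test_period"]],
                        seed = config[["seed"]] + 2L)
    else
      horizon_sweep(raw, w = config[["w"]], h_range = config[["h_range"]] %||% 1:7,
                    models = specs, scheme = config[["scheme"]][["name"]],
                    T = config[["scheme"]][["T"]],
                    partition_length = config[["scheme"]][["partition_length"]],
                    train_period = config[["scheme"]][["train_period"]],
                    test_period = config[["scheme"]][["test_period"]],
                    seed = config[["seed"]] + 2L)
    path <- file.path(out_dir, paste0(sub("-", "_", subcommand), ".csv"))
    utils::write.csv(sw$table, path, row.names = FALSE)
    artifacts <- list(table = path)
  } else if (subcommand == "check") {
    ds <- pipeline_windows(config)
    mcmc <- pipeline_mcmc(config)
    fit <- if (config[["model"]] == "hier_ordinal")
      fit_hier_ordinal(ds, mcmc = mcmc)
    else fit_hier_linear(ds, mcmc = mcmc)
    rep <- posterior_predictive_replicate(fit, ds, seed = config[["seed"]] + 3L)
    path <- file.path(out_dir, "tail_check.csv")
    utils::write.csv(rep$tail_report, path, row.names = FALSE)
    artifacts <- list(tail_check = path)
  } else if (subcommand == "importance") {
    ds <- pipeline_windows(config)
    fit <- fit_hier_linear(ds, mcmc = pipeline_mcmc(config))
    path <- file.path(out_dir, "importance.csv")
    utils::write.csv(feature_importance(fit), path, row.names = FALSE)
    artifacts <- list(importance = path)
  }

  jsonlite::write_json(config, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  artifacts$config <- file.path(out_dir, "resolved_config.json")
  invisible(artifacts)
}
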
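#' Pipeline configuration
#'
#' Exactly one data source must be active: a dataset (path or run table) or
#' the synthetic generator. Supplying `weights_path` instead switches the
#' pipeline to skip-training mode, where only the importance analysis is run
#' on a stored weight table.
#'
#' @param dataset Path to a canonical CSV, or a run table.
#' @param generator A [generator_config()] (used with `n_runs`).
#' @param n_runs Campaign size when generating.
#' @param weights_path Optional weight-table CSV; activates skip-training
#'   mode.
#' @param split_ratios Train/validation/test proportions.
#' @param seed Master seed; all stage seeds derive from it.
#' @param arch An [arch_config()] for the neuron sweep.
#' @param iteration_checkpoints Checkpoints of the iteration sweep.
#' @param max_iterations Iteration-sweep length.
#' @param final_config [training_config()] for the final fit (800 epochs by
#'   default, the plateau of the iteration sweep).
#' @param space [design_space()] used for validation and extrapolation
#'   flags.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = NULL, generator = NULL, n_runs = 77,
                            weights_path = NULL,
                            split_ratios = c(75, 15, 10), seed = 1L,
                            arch = arch_config(seed = seed),
                            iteration_checkpoints = seq(100, 1000, by = 100),
                            max_iterations = 1000,
                            final_config = training_config(seed = seed),
                            space = design_space()) {
  if (is.null(weights_path) && is.null(dataset) == is.null(generator)) {
    abort("pipeline_config: exactly one of dataset or generator must be given")
  }
  structure(list(dataset = dataset, generator = generator, n_runs = n_runs,
                 weights_path = weights_path, split_ratios = split_ratios,
                 seed = as.integer(seed), arch = arch,
                 iteration_checkpoints = iteration_checkpoints,
                 max_iterations = max_iterations,
                 final_config = final_config, space = space),
            class = "pipeline_config")
}

pipeline_log <- function(lines, path) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  cat(paste0("[", stamp, "] ", lines, "\n"), file = path, append = TRUE, sep = "")
}

#' Run the full modelling pipeline
#'
#' Chains the workflow end to end: load or generate the campaign, validate
#' against the design space, split 75:15:10, fit the normalizer on the
#' training rows, sweep the hidden-layer size, sweep iterations at the
#' selected size, train the final model, evaluate test-set parity and
#' compute the Garson importance of the final weights. All numeric
#' artifacts are written under `out_dir` (sweep.csv, history.csv, a model
#' bundle, parity.csv, importance.csv, run_log.txt, summary.json). A run is
#' fully determined by its config: identical configs give identical numeric
#' artifacts.
#'
#' In skip-training mode (`weights_path` set) only the importance report is
#' produced; the trainer is never touched.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted model and all result tables.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  if (file.exists(log_path)) file.remove(log_path)
  summary <- list(seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)))

  if (!is.null(cfg$weights_path)) {
    pipeline_log("stage importance (skip-training mode)", log_path)
    net <- load_weights(cfg$weights_path)
    report <- importance_report(net)
    readr::write_csv(as_tibble(report), file.path(out_dir, "importance.csv"),
                     progress = FALSE)
    summary$mode <- "skip_training"
    summary$subtotals <- attr(report, "subtotals")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(list(network = net, importance = report)))
  }

  stage <- function(name, expr) {
    pipeline_log(paste("stage", name), log_path)
    tryCatch(expr, error = function(e) {
      pipeline_log(sprintf("stage %s FAILED: %s", name, conditionMessage(e)), log_path)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  runs <- stage("load", {
    if (!is.null(cfg$dataset)) {
      if (is.character(cfg$dataset)) read_runs(cfg$dataset) else as_tibble(cfg$dataset)
    } else {
      synthetic_runs(cfg$n_runs, cfg$generator, seed = cfg$seed)
    }
  })
  violations <- stage("validate", validate_ranges(runs, cfg$space))
  readr::write_csv(violations, file.path(out_dir, "validation.csv"), progress = FALSE)

  split <- stage("split", split_runs(runs, cfg$split_ratios, seed = cfg$seed))
  train <- dplyr::filter(split, .data$split == "train")
  validation <- dplyr::filter(split, .data$split == "validation")
  test <- dplyr::filter(split, .data$split == "test")

  normalizer <- stage("normalize", fit_normalizer(train))

  sweep <- stage("neuron_sweep",
                 sweep_neurons(split, cfg$arch,
                               base_config = cfg$final_config))
  readr::write_csv(sweep, file.path(out_dir, "sweep.csv"), progress = FALSE)
  n_best <- select_architecture(sweep)
  pipeline_log(sprintf("selected hidden size n = %d", n_best), log_path)

  history <- stage("iteration_sweep",
                   sweep_iterations(split, n_best,
                                    max_iterations = cfg$max_iterations,
                                    checkpoints = cfg$iteration_checkpoints,
                                    seed = derive_seed(cfg$seed, 101),
                                    base_config = cfg$final_config))
  readr::write_csv(history, file.path(out_dir, "history.csv"), progress = FALSE)

  model <- stage("final_train", {
    net <- init_network(n_best, seed = derive_seed(cfg$seed, 202))
    train_adam(net, train, validation, normalizer, cfg$final_config)
  })
  write_model_bundle(model, file.path(out_dir, "model"))

  parity <- stage("evaluate", {
    pred <- predict(model, test, space = cfg$space)
    dplyr::bind_rows(
      dplyr::mutate(evaluate_parity(pred$.pred_C_Glc, test$C_Glc_g_L),
                    output = "C_Glc", .before = 1),
      dplyr::mutate(evaluate_parity(pred$.pred_C_Phe, test$C_Phe_g_L),
                    output = "C_Phe", .before = 1))
  })
  readr::write_csv(parity, file.path(out_dir, "parity.csv"), progress = FALSE)

  report <- stage("importance", importance_report(model$network))
  readr::write_csv(as_tibble(report), file.path(out_dir, "importance.csv"),
                   progress = FALSE)

  summary$mode <- "full"
  summary$n_runs <- nrow(runs)
  summary$n_violations <- nrow(violations)
  summary$split_sizes <- list(train = nrow(train), validation = nrow(validation),
                              test = nrow(test))
  summary$selected_n <- n_best
  summary$stage_seeds <- list(split = cfg$seed, sweep = cfg$arch$seed,
                              iteration_sweep = derive_seed(cfg$seed, 101),
                              final_train = derive_seed(cfg$seed, 202))
  summary$parity <- parity
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipeline_log("pipeline complete", log_path)

  invisible(list(runs = runs, split = split, violations = violations,
                 sweep = sweep, selected_n = n_best, history = history,
                 model = model, parity = parity, importance = report))
}

#' Write / read a trained-model bundle
#'
#' A bundle directory holds the weight table (`weights.csv`, the published
#' table layout), a lossless JSON copy (`weights.json`), the normalizer
#' sidecar (`normalizer.json`) and an echo of the training configuration
#' (`config.json`).
#'
#' @param model A `stover_ann`.
#' @param dir Bundle directory.
#' @return `write_model_bundle` returns `model` invisibly;
#'   `read_model_bundle` the reconstructed `stover_ann` (without history).
#' @export
write_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_weights(model$network, file.path(dir, "weights.csv"))
  write_network_json(model$network, file.path(dir, "weights.json"))
  write_normalizer(model$normalizer, file.path(dir, "normalizer.json"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(model)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  net <- read_network_json(file.path(dir, "weights.json"))
  normalizer <- read_normalizer(file.path(dir, "normalizer.json"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- training_config(learning_rate = cfg$learning_rate,
                            batch_size = cfg$batch_size,
                            iterations = cfg$iterations, seed = cfg$seed,
                            checkpoints = cfg$checkpoints,
                            normalize_targets = cfg$normalize_targets)
  structure(list(network = net, normalizer = normalizer, config = config,
                 history = tibble(iteration = integer(), dataset = character(),
                                  output = character(), rmse = numeric())),
            class = "stover_ann")
}

#' Predict outcomes for a conditions table with a stored model
#'
#' Thin wrapper over [predict.stover_ann()] that accepts a bundle directory.
#'
#' @param model A `stover_ann` or a bundle directory path.
#' @param conditions Run table of operating conditions.
#' @param space [design_space()] for extrapolation flags.
#' @return Conditions with `.pred_C_Glc`, `.pred_C_Phe` and `.extrapolated`.
#' @export
predict_runs <- function(model, conditions, space = design_space()) {
  if (is.character(model)) model <- read_model_bundle(model)
  predict(model, conditions, space = space)
}
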
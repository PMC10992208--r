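#' Architecture-search configuration
#'
#' The hidden-layer size is swept over the window given by the empirical
#' rule \eqn{n = \sqrt{i + k} + \alpha} with \eqn{\alpha} an integer
#' constant in 1--10, which for 6 inputs and 2 outputs enumerates the 11
#' candidates 3--13. Each candidate is trained for `iterations` epochs
#' (default 500) with a seed derived from `(seed, n)`, so the sweep result
#' is independent of evaluation order.
#'
#' @param n_inputs,n_outputs Input and output counts (`i`, `k`).
#' @param alpha Integer vector of alpha values (a range like `1:10`).
#' @param iterations Epochs per candidate in [sweep_neurons()].
#' @param seed Base seed; per-candidate seeds are derived from it.
#' @param candidates Optional explicit candidate list overriding the rule.
#' @return An `arch_config` list.
#' @export
arch_config <- function(n_inputs = 6, n_outputs = 2, alpha = 1:10,
                        iterations = 500, seed = 1L, candidates = NULL) {
  if (n_inputs < 1 || n_outputs < 1) abort("arch_config: need i >= 1 and k >= 1")
  if (length(alpha) == 0) abort("arch_config: alpha range is empty")
  structure(list(n_inputs = n_inputs, n_outputs = n_outputs,
                 alpha = as.integer(alpha), iterations = as.integer(iterations),
                 seed = as.integer(seed), candidates = candidates),
            class = "arch_config")
}

#' Candidate hidden-layer sizes
#'
#' All integers from `floor(sqrt(i + k) + min(alpha))` to
#' `round(sqrt(i + k) + max(alpha))` (round half up) inclusive. With the
#' defaults this is 3, 4, ..., 13.
#'
#' @param cfg An [arch_config()].
#' @return Strictly increasing integer vector.
#' @export
#' @examples
#' candidate_sizes()
candidate_sizes <- function(cfg = arch_config()) {
  if (!is.null(cfg$candidates)) return(sort(unique(as.integer(cfg$candidates))))
  base <- sqrt(cfg$n_inputs + cfg$n_outputs)
  lo <- floor(base + min(cfg$alpha))
  hi <- round_half_up(base + max(cfg$alpha))
  as.integer(seq(lo, hi))
}

#' Sweep the hidden-layer size
#'
#' Trains one network per candidate size on the `train` rows of a split run
#' table, recording training and validation RMSE for each output on the
#' original g/L scale after `cfg$iterations` epochs. Candidates are trained
#' independently, each from a fresh seeded initialization.
#'
#' @param runs A run table carrying the `split` column from [split_runs()].
#' @param cfg An [arch_config()].
#' @param base_config A [training_config()] supplying the optimizer settings
#'   (its `iterations` and `seed` are overridden per candidate).
#' @return A `stover_sweep` tibble with columns `n`, `rmse_train_glc`,
#'   `rmse_val_glc`, `rmse_train_phe`, `rmse_val_phe`, `seed`, carrying the
#'   observed output ranges as a `ranges` attribute (used by
#'   [select_architecture()]).
#' @export
sweep_neurons <- function(runs, cfg = arch_config(),
                          base_config = training_config()) {
  runs <- as_tibble(runs)
  if (!"split" %in% names(runs)) abort("sweep_neurons: runs must carry a split column")
  train <- dplyr::filter(runs, .data$split == "train")
  validation <- dplyr::filter(runs, .data$split == "validation")
  if (nrow(validation) == 0) abort("sweep_neurons: no validation rows")
  normalizer <- fit_normalizer(
    train,
    if (base_config$normalize_targets) c(input_vars(), output_vars()) else input_vars())

  rows <- purrr::map_dfr(candidate_sizes(cfg), function(n) {
    seed_n <- derive_seed(cfg$seed, n)
    tc <- training_config(learning_rate = base_config$learning_rate,
                          batch_size = base_config$batch_size,
                          iterations = cfg$iterations, seed = seed_n,
                          normalize_targets = base_config$normalize_targets)
    net <- init_network(n, seed = seed_n)
    model <- train_adam(net, train, validation, normalizer, tc)
    fin <- dplyr::filter(model$history, .data$iteration == cfg$iterations)
    get <- function(ds, out) fin$rmse[fin$dataset == ds & fin$output == out]
    tibble(n = n,
           rmse_train_glc = get("train", "C_Glc"),
           rmse_val_glc = get("validation", "C_Glc"),
           rmse_train_phe = get("train", "C_Phe"),
           rmse_val_phe = get("validation", "C_Phe"),
           seed = seed_n)
  })
  attr(rows, "ranges") <- c(
    glc = diff(range(c(train[[output_vars()[1]]], validation[[output_vars()[1]]]))),
    phe = diff(range(c(train[[output_vars()[2]]], validation[[output_vars()[2]]]))))
  class(rows) <- c("stover_sweep", class(rows))
  rows
}

#' Track RMSE along one training run
#'
#' One seeded training run at a fixed hidden size, with training and
#' validation RMSE recorded at each checkpoint (the iteration-sweep
#' analogue of the neuron sweep).
#'
#' @param runs A split run table (see [split_runs()]).
#' @param n Hidden-layer size.
#' @param max_iterations Total epochs.
#' @param checkpoints Strictly increasing iteration numbers
#'   `<= max_iterations`.
#' @param seed Integer seed.
#' @param base_config Optimizer settings (its iterations/checkpoints/seed
#'   are overridden).
#' @return A `stover_history` tibble (`iteration`, `dataset`, `output`,
#'   `rmse` in g/L).
#' @export
sweep_iterations <- function(runs, n, max_iterations = 1000,
                             checkpoints = seq(100, max_iterations, by = 100),
                             seed = 1L, base_config = training_config()) {
  runs <- as_tibble(runs)
  if (!"split" %in% names(runs)) abort("sweep_iterations: runs must carry a split column")
  train <- dplyr::filter(runs, .data$split == "train")
  validation <- dplyr::filter(runs, .data$split == "validation")
  tc <- training_config(learning_rate = base_config$learning_rate,
                        batch_size = base_config$batch_size,
                        iterations = max_iterations, seed = seed,
                        checkpoints = checkpoints,
                        normalize_targets = base_config$normalize_targets)
  net <- init_network(n, seed = seed)
  train_adam(net, train, validation, normalizer = NULL, config = tc)$history
}

#' Choose the hidden-layer size from a sweep
#'
#' Returns the candidate minimizing the sum over both outputs of validation
#' RMSE divided by that output's observed range (a scale-free combination of
#' the g/L-scale glucose error and the sub-g/L phenolics error). Ties break
#' toward the smaller size.
#'
#' @param sweep A `stover_sweep` from [sweep_neurons()].
#' @return The selected hidden-layer size (integer).
#' @export
select_architecture <- function(sweep) {
  if (nrow(sweep) == 0) abort("select_architecture: empty sweep")
  ranges <- attr(sweep, "ranges") %||% c(glc = 1, phe = 1)
  score <- sweep$rmse_val_glc / ranges[["glc"]] + sweep$rmse_val_phe / ranges[["phe"]]
  ord <- order(score, sweep$n)
  as.integer(sweep$n[ord[1]])
}
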
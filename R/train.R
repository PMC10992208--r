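#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001,
#' mini-batches of 2, 800 iterations (one iteration = one full epoch over
#' the shuffled training set; the final short batch is kept). Targets are
#' normalized alongside the inputs by default and every reported RMSE is
#' computed after denormalization, on the original g/L scale.
#'
#' @param learning_rate Positive Adam step size.
#' @param batch_size Positive integer; must not exceed the training-set size.
#' @param iterations Non-negative integer epoch count.
#' @param seed Integer seed governing shuffling (and nothing else).
#' @param checkpoints Increasing integer iteration numbers at which training
#'   and validation RMSE are recorded; `NULL` records the final iteration
#'   only.
#' @param normalize_targets Whether the outputs are min-max normalized for
#'   optimization (predictions are always reported back on the original
#'   scale).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 2,
                            iterations = 800, seed = 1L,
                            checkpoints = NULL, normalize_targets = TRUE) {
  if (learning_rate <= 0) abort("training_config: learning_rate must be positive")
  if (batch_size < 1) abort("training_config: batch_size must be >= 1")
  if (iterations < 0) abort("training_config: iterations must be >= 0")
  if (!is.null(checkpoints)) {
    checkpoints <- as.integer(checkpoints)
    if (any(diff(checkpoints) <= 0) || any(checkpoints < 1) ||
        any(checkpoints > iterations)) {
      abort("training_config: checkpoints must be strictly increasing and within 1..iterations")
    }
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 checkpoints = checkpoints,
                 normalize_targets = isTRUE(normalize_targets)),
            class = "training_config")
}

# Mean-squared-error loss over all outputs of a batch and its analytic
# gradients via backpropagation. Loss = mean over the 2m prediction entries
# of the squared residual (equal weighting of the two outputs).
ann_gradients <- function(net, X, Y) {
  m <- nrow(X)
  f_h <- activation_fn(net$hidden_activation)
  f_o <- activation_fn(net$output_activation)
  d_h <- activation_deriv(net$hidden_activation)
  d_o <- activation_deriv(net$output_activation)
  H <- f_h(sweep(X %*% t(net$IW), 2, net$b1, "+"))
  P <- f_o(sweep(H %*% t(net$LW), 2, net$b2, "+"))
  R <- P - Y
  loss <- mean(R^2)
  dA2 <- (R * d_o(P)) / (m * ncol(Y))             # d loss / d pre-activation, x2 absorbed
  dA2 <- 2 * dA2
  gLW <- t(dA2) %*% H
  gb2 <- colSums(dA2)
  dH <- (dA2 %*% net$LW) * d_h(H)
  gIW <- t(dH) %*% X
  gb1 <- colSums(dH)
  list(loss = loss, IW = gIW, b1 = gb1, LW = gLW, b2 = gb2)
}

adam_state <- function(net) {
  zero <- function(x) x * 0
  list(m = list(IW = zero(net$IW), b1 = zero(net$b1), LW = zero(net$LW), b2 = zero(net$b2)),
       v = list(IW = zero(net$IW), b1 = zero(net$b1), LW = zero(net$LW), b2 = zero(net$b2)),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (p in c("IW", "b1", "LW", "b2")) {
    state$m[[p]] <- beta1 * state$m[[p]] + (1 - beta1) * grads[[p]]
    state$v[[p]] <- beta2 * state$v[[p]] + (1 - beta2) * grads[[p]]^2
    net[[p]] <- net[[p]] - lr * (state$m[[p]] / c1) / (sqrt(state$v[[p]] / c2) + eps)
  }
  list(net = net, state = state)
}

runs_to_xy <- function(runs, normalizer, normalize_targets, require_outputs = TRUE) {
  Xraw <- as.matrix(as_tibble(runs)[input_vars()])
  X <- Xraw
  for (i in seq_along(input_vars())) {
    X[, i] <- normalize_value(Xraw[, i], input_vars()[i], normalizer)
  }
  Y <- NULL
  if (require_outputs) {
    Yraw <- as.matrix(as_tibble(runs)[output_vars()])
    if (anyNA(Yraw)) abort("training data must have both outputs measured for every run")
    Y <- Yraw
    if (normalize_targets) {
      for (i in seq_along(output_vars())) {
        Y[, i] <- normalize_value(Yraw[, i], output_vars()[i], normalizer)
      }
    }
  }
  list(X = X, Y = Y)
}

# Predictions on the original g/L scale for a run table.
predict_matrix <- function(net, runs, normalizer, normalize_targets) {
  X <- runs_to_xy(runs, normalizer, normalize_targets, require_outputs = FALSE)$X
  P <- forward_pass(net, X)
  if (normalize_targets) {
    for (i in seq_along(output_vars())) {
      P[, i] <- denormalize_value(P[, i], output_vars()[i], normalizer)
    }
  }
  P
}

history_rows <- function(iteration, net, sets, normalizer, normalize_targets) {
  purrr::map_dfr(names(sets), function(nm) {
    runs <- sets[[nm]]
    if (is.null(runs) || nrow(runs) == 0) return(tibble())
    P <- predict_matrix(net, runs, normalizer, normalize_targets)
    Y <- as.matrix(as_tibble(runs)[output_vars()])
    tibble(iteration = iteration, dataset = nm,
           output = unname(output_labels()),
           rmse = c(rmse(P[, 1], Y[, 1]), rmse(P[, 2], Y[, 2])))
  })
}

#' Train a network with mini-batch Adam
#'
#' Minimizes the mean squared error of both outputs jointly on the
#' normalized scale. One iteration is one full pass over the shuffled
#' training set in batches of `config$batch_size` (the final short batch is
#' kept). Adam moments are \eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999},
#' \eqn{\epsilon = 10^{-8}}. Fully reproducible for a fixed seed.
#'
#' @param net A `stover_network` giving the initial parameters.
#' @param train Run table with all inputs and both outputs measured.
#' @param validation Optional run table tracked in the history.
#' @param normalizer A [fit_normalizer()] result; fitted on `train` (inputs
#'   and, if `config$normalize_targets`, outputs) when `NULL`.
#' @param config A [training_config()].
#' @return A `stover_ann` model: the final network plus the normalizer, the
#'   config and a tidy `history` tibble (`iteration`, `dataset`, `output`,
#'   `rmse`) on the original g/L scale.
#' @export
train_adam <- function(net, train, validation = NULL, normalizer = NULL,
                       config = training_config()) {
  train <- as_tibble(train)
  if (nrow(train) == 0) abort("train_adam: empty training set")
  if (config$batch_size > nrow(train)) {
    abort("train_adam: batch_size exceeds training-set size")
  }
  if (is.null(normalizer)) {
    vars <- if (config$normalize_targets) c(input_vars(), output_vars()) else input_vars()
    normalizer <- fit_normalizer(train, vars)
  }
  xy <- runs_to_xy(train, normalizer, config$normalize_targets)
  X <- xy$X; Y <- xy$Y
  n_obs <- nrow(X)
  sets <- list(train = train, validation = validation)
  checkpoints <- config$checkpoints %||%
    (if (config$iterations > 0) config$iterations else integer())

  state <- adam_state(net)
  history <- list()
  set.seed(config$seed)
  if (config$iterations > 0) {
    for (epoch in seq_len(config$iterations)) {
      ord <- sample.int(n_obs)
      for (s in seq(1, n_obs, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1, n_obs)]
        g <- ann_gradients(net, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        step <- adam_step(net, g, state, config$learning_rate)
        net <- step$net; state <- step$state
      }
      if (epoch %in% checkpoints) {
        history[[length(history) + 1]] <-
          history_rows(epoch, net, sets, normalizer, config$normalize_targets)
      }
    }
  }
  history <- if (length(history)) dplyr::bind_rows(history) else
    tibble(iteration = integer(), dataset = character(),
           output = character(), rmse = numeric())
  class(history) <- c("stover_history", class(history))
  structure(list(network = net, normalizer = normalizer, config = config,
                 history = history),
            class = "stover_ann")
}

#' @export
print.stover_ann <- function(x, ...) {
  cat(sprintf("<stover_ann> 6-%d-2 model, %d training iteration(s)\n",
              x$network$n, x$config$iterations))
  fin <- dplyr::filter(x$history, .data$iteration == max(.data$iteration))
  if (nrow(fin)) {
    cat("final RMSE (g/L):\n")
    print(tidyr::pivot_wider(fin, names_from = "output", values_from = "rmse"))
  }
  invisible(x)
}

#' Predict hydrolysate outputs for new operating conditions
#'
#' Normalizes the conditions with the model's stored normalizer, runs the
#' forward pass and reports predictions on the original g/L scale. Rows
#' outside the design space are still predicted but flagged as
#' extrapolations.
#'
#' @param object A `stover_ann` from [train_adam()].
#' @param newdata Run table of conditions (outputs not required).
#' @param space [design_space()] used for the extrapolation flag.
#' @param ... Unused.
#' @return `newdata` with added `.pred_C_Glc`, `.pred_C_Phe` (g/L) and
#'   logical `.extrapolated` columns.
#' @export
predict.stover_ann <- function(object, newdata, space = design_space(), ...) {
  newdata <- as_tibble(newdata)
  if (nrow(newdata) == 0) {
    return(dplyr::mutate(newdata, .pred_C_Glc = numeric(),
                         .pred_C_Phe = numeric(), .extrapolated = logical()))
  }
  P <- predict_matrix(object$network, newdata, object$normalizer,
                      object$config$normalize_targets)
  viol <- validate_ranges(newdata, space)
  ids <- if ("run_id" %in% names(newdata)) as.character(newdata$run_id) else
    as.character(seq_len(nrow(newdata)))
  newdata$.pred_C_Glc <- P[, 1]
  newdata$.pred_C_Phe <- P[, 2]
  newdata$.extrapolated <- ids %in% viol$run_id
  newdata
}
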
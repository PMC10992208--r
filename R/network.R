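# Single-hidden-layer feedforward network with the fixed 6-input / 2-output
# topology (6-n-2). Weight conventions follow the field's notation:
# IW[j, i] is the weight from input i to hidden node j, LW[k, j] the weight
# from hidden node j to output k, b1 the hidden biases, b2 the output biases.

activation_fn <- function(name) {
  switch(name,
    tanh = tanh,
    logistic = plogis,
    identity = identity,
    abort(sprintf("unknown activation: %s", name))
  )
}

# Derivative expressed in terms of the activation *value* (cheap for
# tanh/logistic, which is why these two are the supported saturating choices).
activation_deriv <- function(name) {
  switch(name,
    tanh = function(a) 1 - a^2,
    logistic = function(a) a * (1 - a),
    identity = function(a) rep(1, length(a)),
    abort(sprintf("unknown activation: %s", name))
  )
}

#' Construct network parameters from explicit matrices
#'
#' @param IW Numeric `n x 6` hidden-layer weight matrix (`IW[j, i]` connects
#'   input `i` to hidden node `j`).
#' @param b1 Numeric hidden bias vector of length `n`.
#' @param LW Numeric `2 x n` output weight matrix (`LW[k, j]` connects hidden
#'   node `j` to output `k`).
#' @param b2 Numeric output bias vector of length 2.
#' @param hidden_activation,output_activation Activation identifiers; one of
#'   `"tanh"`, `"logistic"`, `"identity"`.
#' @return A `stover_network` object.
#' @export
new_network <- function(IW, b1, LW, b2,
                        hidden_activation = "tanh",
                        output_activation = "identity") {
  IW <- as.matrix(IW); LW <- as.matrix(LW)
  n <- nrow(IW)
  if (ncol(IW) != 6) abort("new_network: IW must have 6 columns (inputs)")
  if (length(b1) != n) abort("new_network: length(b1) must equal nrow(IW)")
  if (!all(dim(LW) == c(2, n))) abort("new_network: LW must be 2 x n")
  if (length(b2) != 2) abort("new_network: b2 must have length 2")
  if (!all(is.finite(IW)) || !all(is.finite(b1)) ||
      !all(is.finite(LW)) || !all(is.finite(b2))) {
    abort("new_network: all parameters must be finite")
  }
  activation_fn(hidden_activation); activation_fn(output_activation)
  structure(
    list(n = n, IW = unname(IW), b1 = as.numeric(b1),
         LW = unname(LW), b2 = as.numeric(b2),
         hidden_activation = hidden_activation,
         output_activation = output_activation),
    class = "stover_network"
  )
}

#' Seeded random initialization of a 6-n-2 network
#'
#' Weights are drawn uniformly from (-0.5, 0.5); biases start at zero.
#'
#' @param n Hidden-layer size (>= 1).
#' @param seed Integer seed; the same seed reproduces the parameters exactly.
#' @inheritParams new_network
#' @return A `stover_network`.
#' @export
#' @examples
#' net <- init_network(12, seed = 7)
#' dim(net$IW)
init_network <- function(n, seed = 1L,
                         hidden_activation = "tanh",
                         output_activation = "identity") {
  if (length(n) != 1 || is.na(n) || n < 1) abort("init_network: n must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  IW <- matrix(runif(n * 6, -0.5, 0.5), nrow = n, ncol = 6)
  LW <- matrix(runif(2 * n, -0.5, 0.5), nrow = 2, ncol = n)
  new_network(IW, numeric(n), LW, numeric(2),
              hidden_activation = hidden_activation,
              output_activation = output_activation)
}

#' @export
print.stover_network <- function(x, ...) {
  cat(sprintf("<stover_network> 6-%d-2 (%s hidden, %s output)\n",
              x$n, x$hidden_activation, x$output_activation))
  invisible(x)
}

#' Forward pass through the network
#'
#' Computes \eqn{\hat y_k = f_{out}(b_{2,k} + \sum_j LW_{k,j}
#' f_{hid}(b_{1,j} + \sum_i IW_{j,i} x_i))} for one input vector or a matrix
#' of row vectors. Inputs are expected on the normalized scale.
#'
#' @param net A `stover_network`.
#' @param x Numeric vector of length 6, or an `m x 6` matrix / data frame of
#'   normalized inputs.
#' @return For a vector input, a named length-2 vector (`C_Glc_g_L`,
#'   `C_Phe_g_L` on whatever scale the network was trained on); for a matrix,
#'   an `m x 2` matrix.
#' @export
forward_pass <- function(net, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != 6) abort("forward_pass: inputs must have 6 columns")
  if (!all(is.finite(X))) abort("forward_pass: inputs must be finite")
  f_h <- activation_fn(net$hidden_activation)
  f_o <- activation_fn(net$output_activation)
  H <- f_h(sweep(X %*% t(net$IW), 2, net$b1, "+"))
  Y <- f_o(sweep(H %*% t(net$LW), 2, net$b2, "+"))
  colnames(Y) <- output_vars()
  if (single) Y[1, ] else Y
}

#' Root-mean-square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{m}\sum_{h=1}^m (y^{(h)}_{pre} -
#' \hat y^{(h)}_{exp})^2}}, the accuracy metric used throughout the
#' architecture and iteration sweeps, reported on the original g/L scale.
#'
#' @param pred,obs Equal-length numeric vectors of predictions and
#'   measurements.
#' @return A single non-negative number.
#' @export
#' @examples
#' rmse(c(1, -1), c(0, 0))
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("rmse: pred and obs lengths differ")
  if (length(pred) == 0) abort("rmse: empty input")
  sqrt(mean((pred - obs)^2))
}

#' Parity evaluation of predictions against measurements
#'
#' Ordinary least-squares fit of predictions on measurements (with
#' intercept); a slope and coefficient of determination near 1 indicate an
#' accurate model.
#'
#' @param pred,obs Numeric vectors, length >= 2; `obs` must not be constant.
#' @return A one-row tibble with `slope`, `r_squared`, `intercept`, `n`.
#' @export
#' @examples
#' evaluate_parity(c(1, 2, 3), c(1, 2, 3))
evaluate_parity <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("evaluate_parity: lengths differ")
  if (length(obs) < 2) abort("evaluate_parity: need at least two points")
  if (sd(obs) == 0) abort("evaluate_parity: observed values are constant")
  fit <- lm(pred ~ obs)
  # R^2 of the parity fit computed directly (summary.lm warns on exact fits)
  sst <- sum((pred - mean(pred))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  tibble(slope = unname(coef(fit)[2]),
         r_squared = r2,
         intercept = unname(coef(fit)[1]),
         n = length(obs))
}
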
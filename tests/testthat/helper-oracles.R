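# Independent brute-force oracles, written before (and kept independent of)
# the vectorised implementations they check.

# Forward pass by explicit double loops over nodes.
forward_oracle <- function(net, x) {
  f_h <- switch(net$hidden_activation, tanh = tanh, logistic = plogis,
                identity = identity)
  f_o <- switch(net$output_activation, tanh = tanh, logistic = plogis,
                identity = identity)
  h <- numeric(net$n)
  for (j in seq_len(net$n)) {
    a <- net$b1[j]
    for (i in 1:6) a <- a + net$IW[j, i] * x[i]
    h[j] <- f_h(a)
  }
  y <- numeric(2)
  for (k in 1:2) {
    a <- net$b2[k]
    for (j in seq_len(net$n)) a <- a + net$LW[k, j] * h[j]
    y[k] <- f_o(a)
  }
  y
}

# Garson partitioning by explicit nested summation over (i, j).
garson_oracle <- function(IW, LW_k) {
  n <- nrow(IW)
  num <- numeric(6)
  for (i in 1:6) {
    for (j in seq_len(n)) {
      num[i] <- num[i] + (abs(IW[j, i]) / sum(abs(IW[j, ]))) * abs(LW_k[j])
    }
  }
  num / sum(num)
}

# Random network with signed weights (includes negatives, unlike init_network
# biases-zero convention).
random_network <- function(n, seed) {
  set.seed(seed)
  new_network(matrix(rnorm(n * 6), n, 6), rnorm(n),
              matrix(rnorm(2 * n), 2, n), rnorm(2))
}

# Central finite differences of the training loss w.r.t. every parameter.
fd_gradients <- function(net, X, Y, eps = 1e-6) {
  loss_at <- function(nn) {
    P <- forward_pass(nn, X)
    mean((P - Y)^2)
  }
  grad_of <- function(param) {
    g <- net[[param]]
    for (idx in seq_along(g)) {
      up <- net; up[[param]][idx] <- up[[param]][idx] + eps
      dn <- net; dn[[param]][idx] <- dn[[param]][idx] - eps
      g[idx] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    g
  }
  list(IW = grad_of("IW"), b1 = grad_of("b1"),
       LW = grad_of("LW"), b2 = grad_of("b2"))
}

# Small in-range run table with measured outputs, built in code.
toy_runs <- function(n = 20, seed = 1) {
  simulate_runs(generate_design(n, seed = seed),
                generator_config(noise_cv = 0.05), seed = seed + 100)
}

# Run table whose normalized targets are exactly reproducible linear maps of
# single inputs (used for representability checks).
linear_runs <- function(n = 40, seed = 3) {
  d <- generate_design(n, seed = seed)
  d$C_Glc_g_L <- d$C_IA_mol_L
  d$C_Phe_g_L <- d$T_C
  d
}
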
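test_that("init_network is seeded, shaped 6-n-2 and rejects n < 1", {
  a <- init_network(12, seed = 7)
  b <- init_network(12, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, init_network(12, seed = 8)))

  net <- init_network(3, seed = 0)
  expect_equal(dim(net$IW), c(3, 6))
  expect_equal(dim(net$LW), c(2, 3))
  expect_equal(net$b1, rep(0, 3))
  expect_true(all(abs(net$IW) < 0.5))
  expect_error(init_network(0, seed = 0), "n must be")
})

test_that("forward_pass reduces to the biases for a zero-weight network", {
  net <- new_network(matrix(0, 4, 6), rep(0, 4), matrix(0, 2, 4), c(1.5, -2))
  expect_equal(unname(forward_pass(net, rep(3, 6))), c(1.5, -2))
  # tanh(0) = 0 with zero biases
  net0 <- new_network(matrix(0.3, 4, 6), rep(0, 4), matrix(1, 2, 4), c(0, 0))
  expect_equal(unname(forward_pass(net0, rep(0, 6))), c(0, 0))
  expect_error(forward_pass(net, rep(0, 5)), "6 columns")
})

test_that("forward_pass at the origin of the published weights equals b2 + LW tanh(b1)", {
  net <- load_table3_weights()
  got <- forward_pass(net, rep(0, 6))
  expect_equal(unname(got), forward_oracle(net, rep(0, 6)), tolerance = 1e-14)
  expect_equal(unname(got), net$b2 + as.numeric(net$LW %*% tanh(net$b1)),
               tolerance = 1e-14)
})

test_that("forward_pass matches the explicit double-loop oracle on random networks", {
  worst <- 0
  for (r in 1:100) {
    net <- random_network(n = 2 + (r %% 7), seed = 1000 + r)
    set.seed(2000 + r)
    x <- rnorm(6)
    worst <- max(worst, max(abs(unname(forward_pass(net, x)) - forward_oracle(net, x))))
  }
  expect_lt(worst, 1e-12)
})

test_that("rmse matches hand-computed values and rejects bad input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(3, 0), 3)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_error(rmse(1:3, 1:2), "lengths")
  expect_error(rmse(numeric(), numeric()), "empty")
})

test_that("rmse is permutation invariant and scales linearly", {
  set.seed(5)
  p <- rnorm(30); o <- rnorm(30)
  perm <- sample(30)
  expect_equal(rmse(p, o), rmse(p[perm], o[perm]))
  expect_equal(rmse(2.5 * p, 2.5 * o), 2.5 * rmse(p, o))
})

test_that("evaluate_parity recovers exact and noisy linear relations", {
  x <- c(1, 2, 4, 7)
  perfect <- evaluate_parity(x, x)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$r_squared, 1)
  doubled <- evaluate_parity(2 * x, x)
  expect_equal(doubled$slope, 2)
  expect_equal(doubled$r_squared, 1)

  set.seed(99)
  obs <- runif(100, 5, 25)
  pred <- obs + rnorm(100, sd = 0.5)
  got <- evaluate_parity(pred, obs)
  # closed-form least squares
  slope_oracle <- sum((obs - mean(obs)) * (pred - mean(pred))) / sum((obs - mean(obs))^2)
  expect_equal(got$slope, slope_oracle, tolerance = 1e-12)
  expect_gt(got$slope, 0.9); expect_lt(got$slope, 1.1)
  expect_error(evaluate_parity(c(1, 2), c(3, 3)), "constant")
})

test_that("the published weight table loads verbatim", {
  net <- load_table3_weights()
  expect_equal(net$n, 12)
  expect_equal(net$IW[1, 1], 0.4211)
  expect_equal(net$IW[12, 2], 0.5409)
  expect_equal(net$b1[1], -0.0095)
  expect_equal(net$LW[1, 4], 0.6842)
  expect_equal(net$LW[2, 10], 0.6152)
  expect_equal(net$b2, c(-0.0381, -0.0051))
})

test_that("weight tables round-trip and malformed tables are rejected", {
  net <- random_network(5, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  save_weights(net, path)
  back <- load_weights(path)
  expect_equal(back$IW, net$IW)
  expect_equal(back$b1, net$b1)
  expect_equal(back$LW, net$LW)
  expect_equal(back$b2, net$b2)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, jpath)
  expect_equal(read_network_json(jpath)$IW, net$IW)

  # node index not running 1..n means a dimension mismatch
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$node_j <- c(1:4, 6)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path2, na = "")
  expect_error(load_weights(path2), "node_j")

  df2 <- readr::read_csv(path, show_col_types = FALSE)
  df2$IW_j3[2] <- NA
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df2, path3, na = "")
  expect_error(load_weights(path3), "malformed")
})
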
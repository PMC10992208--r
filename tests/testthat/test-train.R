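test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (r in 1:5) {
    net <- random_network(n = 3 + r %% 3, seed = 500 + r)
    set.seed(600 + r)
    X <- matrix(runif(5 * 6, -1, 1), 5, 6)
    Y <- matrix(runif(5 * 2, -1, 1), 5, 2)
    got <- stovernet:::ann_gradients(net, X, Y)
    fd <- fd_gradients(net, X, Y)
    for (p in c("IW", "b1", "LW", "b2")) {
      rel <- abs(got[[p]] - fd[[p]]) / pmax(abs(fd[[p]]), 1e-3)
      worst <- max(worst, max(rel))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("zero iterations returns the initial parameters unchanged", {
  runs <- toy_runs(10, seed = 4)
  net <- init_network(4, seed = 4)
  m <- train_adam(net, runs, config = training_config(iterations = 0, seed = 4))
  expect_identical(m$network$IW, net$IW)
  expect_identical(m$network$LW, net$LW)
  expect_equal(nrow(m$history), 0)
})

test_that("training is bitwise reproducible under a fixed seed", {
  runs <- toy_runs(16, seed = 6)
  cfg <- training_config(iterations = 20, seed = 11, checkpoints = c(5, 10, 20))
  m1 <- train_adam(init_network(5, seed = 2), runs, runs[1:4, ], config = cfg)
  m2 <- train_adam(init_network(5, seed = 2), runs, runs[1:4, ], config = cfg)
  expect_identical(m1$network, m2$network)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$history$iteration[m1$history$dataset == "train"][c(1, 3, 5)],
               c(5, 10, 20))
})

test_that("a representable linear map is fitted to near machine-noise RMSE", {
  d <- linear_runs(40, seed = 3)
  m <- train_adam(init_network(3, seed = 3), d,
                  config = training_config(iterations = 800, seed = 3))
  P <- stovernet:::predict_matrix(m$network, d, m$normalizer, TRUE)
  r_glc <- rmse(normalize_value(P[, 1], "C_Glc_g_L", m$normalizer),
                normalize_value(d$C_Glc_g_L, "C_Glc_g_L", m$normalizer))
  r_phe <- rmse(normalize_value(P[, 2], "C_Phe_g_L", m$normalizer),
                normalize_value(d$C_Phe_g_L, "C_Phe_g_L", m$normalizer))
  expect_lt(r_glc, 0.05)
  expect_lt(r_phe, 0.05)
  # exact least-squares oracle: the normalized targets are exact affine maps
  # of single inputs, so the residual floor is zero
  X <- stovernet:::runs_to_xy(d, m$normalizer, TRUE)$X
  y <- normalize_value(d$C_Glc_g_L, "C_Glc_g_L", m$normalizer)
  ls_rmse <- sqrt(mean(stats::lm.fit(cbind(1, X), y)$residuals^2))
  expect_lt(abs(r_glc - ls_rmse), 0.05)
})

test_that("a noiseless 6-12-2 teacher function is recovered on held-out data", {
  set.seed(11)
  teacher <- init_network(12, seed = 42)
  X <- matrix(runif(77 * 6, -1, 1), 77, 6)
  Y <- forward_pass(teacher, X)
  d <- tibble::tibble(run_id = as.character(1:77),
                      C_IA_mol_L = X[, 1], T_C = X[, 2], t_min = X[, 3],
                      R_SL_frac = X[, 4], k_IA = X[, 5], E_FPU_g = X[, 6],
                      C_Glc_g_L = Y[, 1], C_Phe_g_L = Y[, 2])
  sp <- split_runs(d, seed = 11)
  tr <- dplyr::filter(sp, split == "train")
  te <- dplyr::filter(sp, split == "test")
  m <- train_adam(init_network(12, seed = 11), tr,
                  config = training_config(iterations = 800, seed = 11))
  pred <- predict(m, te)
  expect_lt(rmse(pred$.pred_C_Glc, te$C_Glc_g_L),
            0.02 * diff(range(d$C_Glc_g_L)))
  expect_lt(rmse(pred$.pred_C_Phe, te$C_Phe_g_L),
            0.02 * diff(range(d$C_Phe_g_L)))
})

test_that("train_adam validates its inputs", {
  runs <- toy_runs(6, seed = 9)
  expect_error(train_adam(init_network(3, 1), runs[0, ]), "empty")
  expect_error(train_adam(init_network(3, 1), runs,
                          config = training_config(batch_size = 7)),
               "batch_size")
  incomplete <- runs
  incomplete$C_Phe_g_L[2] <- NA
  expect_error(train_adam(init_network(3, 1), incomplete,
                          config = training_config(iterations = 1)),
               "outputs")
})

test_that("tidy and glance summarise a fitted model", {
  runs <- toy_runs(12, seed = 13)
  m <- train_adam(init_network(4, seed = 13), runs,
                  config = training_config(iterations = 5, seed = 13))
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 6 + 4 + 2 * 4 + 2)
  expect_true(all(c("layer", "term", "estimate") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_hidden, 4)
  expect_equal(gl$n_params, 38)
  expect_true("rmse_train_C_Glc" %in% names(gl))
})
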
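test_that("the empirical rule enumerates the 3..13 candidate window", {
  expect_equal(candidate_sizes(), 3:13)
  expect_length(candidate_sizes(), 11)
  expect_equal(candidate_sizes(arch_config(n_inputs = 2, n_outputs = 2, alpha = 1)), 3L)
  expect_equal(candidate_sizes(arch_config(alpha = 1)), c(3L, 4L))
  expect_equal(candidate_sizes(arch_config(candidates = c(12, 5, 5))), c(5L, 12L))
  expect_error(arch_config(alpha = integer()), "alpha")
})

test_that("candidate lists are strictly increasing positive integers", {
  set.seed(14)
  for (r in 1:20) {
    cfg <- arch_config(n_inputs = sample(1:10, 1), n_outputs = sample(1:4, 1),
                       alpha = sort(sample(1:10, sample(1:3, 1))))
    cs <- candidate_sizes(cfg)
    expect_true(all(diff(cs) > 0))
    expect_true(all(cs >= 1))
    expect_identical(cs, as.integer(cs))
  }
})

test_that("sweep_neurons trains one row per candidate, deterministically", {
  runs <- split_runs(toy_runs(24, seed = 17), seed = 17)
  cfg <- arch_config(candidates = c(3, 5), iterations = 15, seed = 17)
  sw1 <- sweep_neurons(runs, cfg)
  sw2 <- sweep_neurons(runs, cfg)
  expect_equal(nrow(sw1), 2)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_true(all(c("n", "rmse_train_glc", "rmse_val_glc",
                    "rmse_train_phe", "rmse_val_phe", "seed") %in% names(sw1)))
  expect_true(all(sw1[, 2:5] >= 0))

  single <- sweep_neurons(runs, arch_config(candidates = 4, iterations = 15, seed = 17))
  expect_equal(nrow(single), 1)
})

test_that("sweep_iterations records the requested checkpoints and validates them", {
  runs <- split_runs(toy_runs(24, seed = 18), seed = 18)
  hist <- sweep_iterations(runs, n = 3, max_iterations = 10,
                           checkpoints = c(5, 10), seed = 18)
  expect_equal(sort(unique(hist$iteration)), c(5, 10))
  # 2 checkpoints x 2 datasets x 2 outputs
  expect_equal(nrow(hist), 8)
  one <- sweep_iterations(runs, n = 3, max_iterations = 1, checkpoints = 1, seed = 18)
  expect_equal(unique(one$iteration), 1L)
  expect_error(sweep_iterations(runs, 3, max_iterations = 10,
                                checkpoints = c(10, 5), seed = 1),
               "checkpoints")
})

test_that("on representable noiseless data more iterations do not hurt validation RMSE", {
  d <- split_runs(linear_runs(40, seed = 19), seed = 19)
  hist <- sweep_iterations(d, n = 3, max_iterations = 800,
                           checkpoints = c(100, 800), seed = 19)
  val <- dplyr::filter(hist, dataset == "validation")
  for (out in unique(val$output)) {
    v <- dplyr::filter(val, output == out)
    expect_lte(v$rmse[v$iteration == 800], v$rmse[v$iteration == 100])
  }
})

test_that("select_architecture minimises range-normalised validation RMSE with ties to smaller n", {
  sweep <- tibble::tibble(n = c(3, 12, 13),
                          rmse_train_glc = 1, rmse_train_phe = 1,
                          rmse_val_glc = c(7, 4, 5), rmse_val_phe = c(0.4, 0.2, 0.3),
                          seed = 1)
  attr(sweep, "ranges") <- c(glc = 17.5, phe = 2.2)
  expect_equal(select_architecture(sweep), 12L)

  tied <- tibble::tibble(n = c(9, 5), rmse_val_glc = c(2, 2), rmse_val_phe = c(0.1, 0.1))
  expect_equal(select_architecture(tied), 5L)
  expect_equal(select_architecture(tied[1, ]), 9L)
  expect_error(select_architecture(tied[0, ]), "empty")
})

test_that("sweep results do not depend on candidate evaluation order", {
  runs <- split_runs(toy_runs(24, seed = 20), seed = 20)
  fwd <- sweep_neurons(runs, arch_config(candidates = c(3, 4), iterations = 10, seed = 20))
  rev <- sweep_neurons(runs, arch_config(candidates = c(4, 3), iterations = 10, seed = 20))
  expect_identical(as.data.frame(fwd), as.data.frame(rev))
})
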
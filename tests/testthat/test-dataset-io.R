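test_that("the bundled acid-series fixture reads as 15 runs with the quoted outcomes", {
  runs <- fig2_runs()
  expect_equal(nrow(runs), 15)
  expect_identical(names(runs), c("run_id", input_vars(), output_vars()))
  hcl <- runs[runs$k_IA == 1 & runs$C_IA_mol_L == 0.05, ]
  expect_equal(hcl$C_Glc_g_L, 22.8)
  expect_equal(hcl$C_Phe_g_L, 1.13)
  expect_equal(runs$C_Glc_g_L[runs$k_IA == 2 & runs$C_IA_mol_L == 0.05], 25.6)
  expect_equal(runs$C_Phe_g_L[runs$k_IA == 3 & runs$C_IA_mol_L == 0.05], 1.97)
  expect_equal(runs$C_Phe_g_L[runs$k_IA == 1 & runs$C_IA_mol_L == 0.1], 1.64)
  # unmeasured outcomes stay empty
  expect_equal(sum(is.na(runs$C_Glc_g_L)), 12)
})

test_that("read_runs handles headers-only files, schema errors and bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(canonical_cols(), collapse = ","), path)
  expect_equal(nrow(read_runs(path)), 0)

  # file lacking the enzyme-dose column
  runs <- toy_runs(3)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(runs[setdiff(names(runs), "E_FPU_g")], path2)
  expect_error(read_runs(path2), "E_FPU_g")

  path3 <- withr::local_tempfile(fileext = ".csv")
  bad <- runs
  bad$T_C <- as.character(bad$T_C)
  bad$T_C[2] <- "hot"
  readr::write_csv(bad, path3)
  expect_error(read_runs(path3), "row 2")
})

test_that("write/read round-trips numerically and normalizes percent ratios", {
  runs <- toy_runs(25, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_runs(runs, path)
  back <- read_runs(path)
  expect_identical(back$run_id, runs$run_id)
  for (v in c(input_vars(), output_vars())) {
    expect_equal(back[[v]], runs[[v]], tolerance = 1e-6)
  }

  # R_SL quoted as a percent (bare or suffixed) becomes a fraction
  path2 <- withr::local_tempfile(fileext = ".csv")
  pct <- runs[1:2, ]
  pct$R_SL_frac <- c("12.5%", "14")
  readr::write_csv(pct, path2)
  expect_equal(read_runs(path2)$R_SL_frac, c(0.125, 0.14))
})

test_that("validate_ranges flags exactly the out-of-range records", {
  ok <- tibble::tibble(run_id = "ok", k_IA = 2, C_IA_mol_L = 0.3, T_C = 160,
                       t_min = 40, R_SL_frac = 0.10, E_FPU_g = 20)
  expect_equal(nrow(validate_ranges(ok)), 0)

  bad_cia <- dplyr::mutate(ok, run_id = "a", C_IA_mol_L = 0.7)
  v <- validate_ranges(bad_cia)
  expect_equal(nrow(v), 1)
  expect_equal(v$variable, "C_IA_mol_L")

  bad_k <- dplyr::mutate(ok, run_id = "b", k_IA = 4)
  expect_equal(validate_ranges(bad_k)$variable, "k_IA")
})

test_that("validate_ranges agrees with a brute-force per-field interval check", {
  set.seed(42)
  space <- design_space()
  # jitter a valid design so some values fall outside each interval
  runs <- generate_design(60, seed = 42)
  for (v in space$variable) {
    w <- diff(range(runs[[v]]))
    runs[[v]] <- runs[[v]] + rnorm(60, sd = 0.4 * w)
  }
  runs$k_IA <- sample(0:5, 60, replace = TRUE)
  got <- validate_ranges(runs, space)

  expected <- 0L
  for (r in seq_len(60)) {
    for (i in seq_len(nrow(space))) {
      x <- runs[[space$variable[i]]][r]
      if (x < space$lower[i] || x > space$upper[i]) expected <- expected + 1L
    }
    if (!runs$k_IA[r] %in% 1:3) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
  # every flagged row really is out of range
  for (r in seq_len(nrow(got))) {
    expect_true(got$value[r] < got$lower[r] || got$value[r] > got$upper[r])
  }
})

test_that("the 75:15:10 split of 77 runs yields 57/12/8", {
  runs <- tibble::tibble(run_id = sprintf("r%02d", 1:77))
  sizes <- table(split_runs(runs, seed = 5)$split)
  expect_equal(unname(c(sizes)), c(57, 12, 8))
})

test_that("split_runs partitions exactly for any size and seed", {
  for (n in c(1:10, sample(11:200, 25))) {
    seed <- n * 13L
    runs <- tibble::tibble(run_id = as.character(seq_len(n)))
    sp <- split_runs(runs, seed = seed)
    expect_equal(sort(sp$run_id), sort(runs$run_id))
    expect_false(anyNA(sp$split))
    sizes <- c(table(sp$split))
    expect_equal(sum(sizes), n)
    expect_equal(unname(sizes[["train"]]), floor(n * 0.75))
  }
})

test_that("split_runs is deterministic, honours degenerate ratios and rejects bad input", {
  runs <- tibble::tibble(run_id = as.character(1:20))
  expect_identical(split_runs(runs, seed = 9), split_runs(runs, seed = 9))

  all_train <- split_runs(runs, ratios = c(100, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  expect_error(split_runs(runs[0, ]), "empty")
  expect_error(split_runs(runs, ratios = c(0, 0, 0)), "ratios")
})
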
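#' Read a table of experimental runs from CSV
#'
#' Reads the canonical comma-delimited schema (`run_id, k_IA, C_IA_mol_L,
#' T_C, t_min, R_SL_frac, E_FPU_g, C_Glc_g_L, C_Phe_g_L`; UTF-8, `.` decimal
#' separator). Output columns may be empty for unmeasured runs. A `schema`
#' map allows reading files whose headers differ from the canonical names.
#'
#' Solid-to-liquid ratios written as percentages (a `%` suffix or a value
#' greater than 1) are converted to fractions, since the design is quoted
#' both ways (10--15% vs 0.10).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(T_C = "temperature")`.
#' @return A tibble with the canonical columns, one row per run, in file
#'   order. A missing `run_id` column is filled with `run_001, run_002, ...`.
#' @export
read_runs <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("read_runs: file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- setdiff(canonical_cols(), "run_id")
  lookup <- setNames(needed, needed)
  if (!is.null(schema)) lookup[names(schema)] <- unname(schema)
  missing <- needed[!unname(lookup[needed]) %in% names(raw)]
  if (length(missing)) {
    abort(sprintf("read_runs: missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(raw))
  id_col <- if (!is.null(schema) && "run_id" %in% names(schema)) schema[["run_id"]] else "run_id"
  out$run_id <- if (id_col %in% names(raw)) as.character(raw[[id_col]]) else
    sprintf("run_%03d", seq_len(nrow(raw)))
  for (v in needed) {
    out[[v]] <- parse_numeric_column(raw[[lookup[[v]]]], v)
  }
  out$R_SL_frac <- normalize_ratio(out$R_SL_frac)
  out <- out[canonical_cols()]
  attr(out, "provenance") <- "measured"
  out
}

# Locale-independent numeric parsing with a row-indexed error; empty cells
# become NA (legitimate for unmeasured outputs).
parse_numeric_column <- function(x, name) {
  x <- trimws(x)
  pct <- grepl("%$", x)
  x[pct] <- sub("%$", "", x[pct])
  empty <- is.na(x) | x == ""
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!empty & is.na(val))
  if (length(bad)) {
    abort(sprintf("read_runs: non-numeric value '%s' in column %s at row %d",
                  x[bad[1]], name, bad[1]))
  }
  val[pct & !is.na(val)] <- val[pct & !is.na(val)] / 100
  val
}

# R_SL quoted as a percent (e.g. 12.5) is normalized to a fraction.
normalize_ratio <- function(x) {
  over <- !is.na(x) & x > 1
  x[over] <- x[over] / 100
  x
}

#' Write runs to CSV in the canonical schema
#'
#' @param runs A data frame of runs.
#' @param path Output path.
#' @return `runs`, invisibly.
#' @export
write_runs <- function(runs, path) {
  runs <- as_tibble(runs)
  cols <- intersect(canonical_cols(), names(runs))
  readr::write_csv(runs[cols], path, progress = FALSE)
  invisible(runs)
}

#' The printed single-factor acid series (15 runs)
#'
#' The fifteen pretreatment batches run at fixed solid-to-liquid ratio 0.10
#' and enzyme dose 20 FPU/g: each of the three acids at five concentrations.
#' The four outcome pairs quoted in the results text are filled in; the other
#' outcomes are left empty.
#'
#' @return A 15-row tibble in the canonical schema.
#' @export
fig2_runs <- function() {
  out <- read_runs(system.file("extdata", "fig2_points.csv", package = "stovernet"))
  attr(out, "provenance") <- "fixture"
  out
}

#' Split runs into training, validation and test groups
#'
#' Partitions the rows by a seeded uniform shuffle into the standard
#' 75:15:10 groups (by default). The training group takes
#' `floor(N * r_train)` rows; the remainder is divided between validation
#' and test in proportion `r_val : (r_val + r_test)`, validation taking the
#' rounded share and test the rest. For the study's 77 runs this yields
#' 57 / 12 / 8.
#'
#' @param runs A non-empty data frame of runs.
#' @param ratios Three non-negative proportions (any scale; normalised to
#'   sum to 1).
#' @param seed Integer seed; the same seed always gives the same partition.
#' @return The input tibble with an added `split` factor column with levels
#'   `train`, `validation`, `test`.
#' @export
#' @examples
#' runs <- tibble::tibble(run_id = as.character(1:77))
#' table(split_runs(runs, seed = 1)$split)
split_runs <- function(runs, ratios = c(75, 15, 10), seed = 1L) {
  runs <- as_tibble(runs)
  n <- nrow(runs)
  if (n == 0) abort("split_runs: dataset is empty")
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) <= 0) {
    abort("split_runs: ratios must be three non-negative numbers with a positive sum")
  }
  r <- ratios / sum(ratios)
  n_train <- floor(n * r[1] + 1e-9)
  rem <- n - n_train
  n_val <- if (r[2] + r[3] > 0) round_half_up(rem * r[2] / (r[2] + r[3])) else 0
  n_test <- rem - n_val
  set.seed(seed)
  ord <- sample.int(n)
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[ord[n_train + seq_len(n_val)]] <- "validation"
  if (n_test > 0) split[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  runs$split <- factor(split, levels = c("train", "validation", "test"))
  runs
}
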
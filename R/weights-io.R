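# Serialization of network parameters.
#
# The CSV layout mirrors the published weight table: one row per hidden node
# j with columns IW_j1..IW_j6, b1_j, LW_1j, LW_2j, and the two output biases
# b2_k carried on rows j = 1, 2 of a trailing b2_k column. A lossless JSON
# form (including activation identifiers) is provided for programmatic use.

weights_csv_cols <- function() {
  c("node_j", paste0("IW_j", 1:6), "b1_j", "LW_1j", "LW_2j", "b2_k")
}

#' Save network parameters as a weight-table CSV
#'
#' @param net A `stover_network`.
#' @param path Output CSV path.
#' @return `net`, invisibly.
#' @export
save_weights <- function(net, path) {
  n <- net$n
  df <- tibble(node_j = seq_len(n))
  for (i in 1:6) df[[paste0("IW_j", i)]] <- net$IW[, i]
  df$b1_j <- net$b1
  df$LW_1j <- net$LW[1, ]
  df$LW_2j <- net$LW[2, ]
  df$b2_k <- c(net$b2, rep(NA_real_, n - 2))
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(net)
}

#' Load network parameters from a weight-table CSV
#'
#' @param path CSV file in the layout written by [save_weights()].
#' @param hidden_activation,output_activation Activation identifiers to
#'   attach (the table format does not store them).
#' @return A `stover_network` with `n` equal to the number of rows.
#' @export
load_weights <- function(path, hidden_activation = "tanh",
                         output_activation = "identity") {
  if (!file.exists(path)) abort(sprintf("load_weights: file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  expected <- weights_csv_cols()
  if (!identical(names(df), expected)) {
    abort(sprintf("load_weights: expected columns %s",
                  paste(expected, collapse = ", ")))
  }
  n <- nrow(df)
  if (n < 2) abort("load_weights: need at least two hidden-node rows (b2 lives on rows 1-2)")
  if (!identical(as.integer(df$node_j), seq_len(n))) {
    abort(sprintf("load_weights: node_j must run 1..%d (dimension mismatch)", n))
  }
  IW <- as.matrix(df[paste0("IW_j", 1:6)])
  LW <- rbind(df$LW_1j, df$LW_2j)
  core <- c(IW, df$b1_j, LW, df$b2_k[1:2])
  if (anyNA(core)) abort("load_weights: malformed row (missing numeric value)")
  new_network(IW, df$b1_j, LW, df$b2_k[1:2],
              hidden_activation = hidden_activation,
              output_activation = output_activation)
}

#' The published 6-12-2 weight set
#'
#' Loads the bundled fixture holding the trained model's weight table
#' verbatim (12 hidden nodes; e.g. `IW[1, 1] = 0.4211`,
#' `b2 = c(-0.0381, -0.0051)`).
#'
#' @inheritParams load_weights
#' @return A `stover_network` with `n = 12`.
#' @export
load_table3_weights <- function(hidden_activation = "tanh",
                                output_activation = "identity") {
  load_weights(system.file("extdata", "table3_weights.csv", package = "stovernet"),
               hidden_activation = hidden_activation,
               output_activation = output_activation)
}

#' Lossless JSON serialization of a network
#'
#' @param net A `stover_network`.
#' @param path JSON file path.
#' @return `write_network_json` returns `net` invisibly; `read_network_json`
#'   the reconstructed network.
#' @export
write_network_json <- function(net, path) {
  payload <- list(
    n = net$n, IW = net$IW, b1 = net$b1, LW = net$LW, b2 = net$b2,
    hidden_activation = net$hidden_activation,
    output_activation = net$output_activation
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_network(p$IW, p$b1, p$LW, p$b2,
              hidden_activation = p$hidden_activation,
              output_activation = p$output_activation)
}
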
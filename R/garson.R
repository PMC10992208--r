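#' Garson connection-weight relative importance
#'
#' Partitions the absolute input-to-hidden weights of a fitted 6-n-2
#' network, scaled by the absolute hidden-to-output weights of one output,
#' into per-input shares that sum to 100%:
#' \deqn{I_i = \frac{\sum_j (|IW_{j,i}| / \sum_{i'} |IW_{j,i'}|)\,|LW_{k,j}|}
#'            {\sum_{i''} \sum_j (|IW_{j,i''}| / \sum_{i'} |IW_{j,i'}|)\,|LW_{k,j}|}.}
#' Biases are not part of the statistic, and it is independent of the
#' activation functions.
#'
#' @param net A `stover_network`.
#' @param output Output index: 1 for glucose (`C_Glc`), 2 for phenolics
#'   (`C_Phe`).
#' @return A `stover_importance` tibble with one row per input: `input`
#'   (display label), `variable` (canonical column), `fraction` (importances
#'   summing to 1), `percent` (round-half-up integer) and `rank`. The output
#'   label is carried in the `output` attribute.
#' @export
#' @examples
#' garson_importance(load_table3_weights(), output = 1)
garson_importance <- function(net, output = 1) {
  if (!(length(output) == 1 && output %in% seq_len(nrow(net$LW)))) {
    abort("garson_importance: output must be 1 or 2")
  }
  W <- abs(net$IW)
  rs <- rowSums(W)
  if (any(rs == 0)) {
    abort("garson_importance: a hidden node has all-zero input weights (zero denominator)")
  }
  contrib <- colSums((W / rs) * abs(net$LW[output, ]))
  frac <- contrib / sum(contrib)
  out <- tibble(
    input = unname(input_labels()),
    variable = input_vars(),
    fraction = unname(frac),
    percent = round_half_up(unname(frac) * 100),
    rank = rank(-frac, ties.method = "min")
  )
  attr(out, "output") <- unname(output_labels()[output])
  class(out) <- c("stover_importance", class(out))
  out
}

#' Relative-importance report for both outputs
#'
#' Evaluates the Garson statistic for glucose and phenolics and summarises
#' the split between the five pretreatment variables (acid concentration,
#' temperature, time, solid-to-liquid ratio, acid kind) and the enzyme dose.
#' Integer percents are round-half-up and are not forced to sum to 100.
#'
#' @param net A `stover_network` with two outputs.
#' @return A `stover_importance_report` tibble with columns `output`,
#'   `input`, `variable`, `fraction`, `percent`, `rank`, plus a `subtotals`
#'   attribute: one row per output with `pretreatment_percent` (sum of the
#'   five pretreatment fractions, as integer percent) and `enzyme_percent`.
#' @export
#' @examples
#' importance_report(load_table3_weights())
importance_report <- function(net) {
  tabs <- purrr::map(1:2, function(k) {
    tab <- garson_importance(net, output = k)
    dplyr::mutate(as_tibble(tab), output = attr(tab, "output"), .before = 1)
  })
  out <- dplyr::bind_rows(tabs)
  subtotals <- purrr::map_dfr(tabs, function(tab) {
    pre <- sum(tab$fraction[tab$variable != "E_FPU_g"])
    tibble(output = tab$output[1],
           pretreatment_percent = round_half_up(pre * 100),
           enzyme_percent = round_half_up((1 - pre) * 100))
  })
  attr(out, "subtotals") <- subtotals
  class(out) <- c("stover_importance_report", class(out))
  out
}

#' @export
print.stover_importance_report <- function(x, ...) {
  cat("Garson relative importance (integer percents, round half up)\n")
  wide <- tidyr::pivot_wider(as_tibble(x)[c("output", "input", "percent")],
                             names_from = "input", values_from = "percent")
  print(wide)
  st <- attr(x, "subtotals")
  for (i in seq_len(nrow(st))) {
    cat(sprintf("%s: pretreatment variables %d%%, enzyme dose %d%%\n",
                st$output[i], st$pretreatment_percent[i], st$enzyme_percent[i]))
  }
  invisible(x)
}
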
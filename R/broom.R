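# broom-style views of fitted objects.

#' Tidy the parameters of a network
#'
#' One row per connection or bias: `layer` (`hidden` / `output`), `term`
#' (e.g. `IW[3,2]`), `from`, `to` and `estimate`.
#'
#' @param x A `stover_network`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stover_network
#' @export
tidy.stover_network <- function(x, ...) {
  inp <- unname(input_labels()); outp <- unname(output_labels())
  hid <- expand.grid(j = seq_len(x$n), i = 1:6)
  out <- expand.grid(k = 1:2, j = seq_len(x$n))
  dplyr::bind_rows(
    tibble(layer = "hidden",
           term = sprintf("IW[%d,%d]", hid$j, hid$i),
           from = inp[hid$i], to = sprintf("h%d", hid$j),
           estimate = x$IW[cbind(hid$j, hid$i)]),
    tibble(layer = "hidden", term = sprintf("b1[%d]", seq_len(x$n)),
           from = "bias", to = sprintf("h%d", seq_len(x$n)),
           estimate = x$b1),
    tibble(layer = "output",
           term = sprintf("LW[%d,%d]", out$k, out$j),
           from = sprintf("h%d", out$j), to = outp[out$k],
           estimate = x$LW[cbind(out$k, out$j)]),
    tibble(layer = "output", term = sprintf("b2[%d]", 1:2),
           from = "bias", to = outp, estimate = x$b2)
  )
}

#' @rdname tidy.stover_network
#' @method tidy stover_ann
#' @export
tidy.stover_ann <- function(x, ...) tidy.stover_network(x$network, ...)

#' One-row summary of a trained model
#'
#' @param x A `stover_ann`.
#' @param ... Unused.
#' @return A one-row tibble: hidden size, parameter count, iterations, and
#'   the final training/validation RMSE per output (g/L) where recorded.
#' @method glance stover_ann
#' @export
glance.stover_ann <- function(x, ...) {
  net <- x$network
  out <- tibble(n_hidden = net$n,
                n_params = length(net$IW) + length(net$b1) +
                  length(net$LW) + length(net$b2),
                iterations = x$config$iterations,
                learning_rate = x$config$learning_rate,
                batch_size = x$config$batch_size)
  h <- x$history
  if (nrow(h)) {
    fin <- dplyr::filter(h, .data$iteration == max(.data$iteration))
    for (i in seq_len(nrow(fin))) {
      out[[sprintf("rmse_%s_%s", fin$dataset[i], fin$output[i])]] <- fin$rmse[i]
    }
  }
  out
}
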
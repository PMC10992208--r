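# ggplot2 views of the result objects. Figures are deliberately plain; the
# tables themselves are the primary artifacts.

#' @import ggplot2
NULL

#' Plot a Garson importance table
#'
#' @param object A `stover_importance` or `stover_importance_report`.
#' @param ... Unused.
#' @return A ggplot: one bar per input (faceted by output for a report).
#' @method autoplot stover_importance
#' @export
autoplot.stover_importance <- function(object, ...) {
  df <- as_tibble(object)
  df$input <- factor(df$input, levels = unname(input_labels()))
  ggplot(df, aes(x = .data$input, y = 100 * .data$fraction)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = paste0(.data$percent, "%")), vjust = -0.3, size = 3) +
    labs(x = NULL, y = "relative importance (%)",
         title = paste("Garson importance,", attr(object, "output"))) +
    theme_minimal()
}

#' @rdname autoplot.stover_importance
#' @method autoplot stover_importance_report
#' @export
autoplot.stover_importance_report <- function(object, ...) {
  df <- as_tibble(object)
  df$input <- factor(df$input, levels = unname(input_labels()))
  ggplot(df, aes(x = .data$input, y = 100 * .data$fraction)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = paste0(.data$percent, "%")), vjust = -0.3, size = 3) +
    facet_wrap(~output) +
    labs(x = NULL, y = "relative importance (%)",
         title = "Garson relative importance of the six operating variables") +
    theme_minimal()
}

#' Plot a training history
#'
#' RMSE (g/L) against iteration count for each output and dataset, the
#' iteration-sweep view used to pick the 800-epoch plateau.
#'
#' @param object A `stover_history` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stover_history
#' @export
autoplot.stover_history <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$iteration, y = .data$rmse, colour = .data$dataset)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~output, scales = "free_y") +
    labs(x = "iterations (epochs)", y = "RMSE (g/L)", colour = NULL) +
    theme_minimal()
}

#' Plot a neuron sweep
#'
#' @param object A `stover_sweep` from [sweep_neurons()].
#' @param ... Unused.
#' @return A ggplot of train/validation RMSE against hidden-layer size.
#' @method autoplot stover_sweep
#' @export
autoplot.stover_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::starts_with("rmse_"),
                              names_to = c("dataset", "output"),
                              names_pattern = "rmse_(train|val)_(glc|phe)",
                              values_to = "rmse")
  long$output <- c(glc = "C_Glc", phe = "C_Phe")[long$output]
  ggplot(long, aes(x = .data$n, y = .data$rmse, colour = .data$dataset)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~output, scales = "free_y") +
    scale_x_continuous(breaks = unique(long$n)) +
    labs(x = "hidden-layer size n", y = "RMSE (g/L)", colour = NULL) +
    theme_minimal()
}

#' Parity plot of predictions against measurements
#'
#' Scatter of predicted versus measured values with the identity line and
#' the least-squares parity fit whose slope and R-squared summarise model
#' accuracy.
#'
#' @param pred,obs Numeric vectors on the original g/L scale.
#' @param output Label for the axis titles.
#' @return A ggplot.
#' @export
plot_parity <- function(pred, obs, output = "output") {
  par_fit <- evaluate_parity(pred, obs)
  ggplot(tibble(pred = pred, obs = obs), aes(x = .data$obs, y = .data$pred)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    geom_point() +
    labs(x = sprintf("measured %s (g/L)", output),
         y = sprintf("predicted %s (g/L)", output),
         title = sprintf("Parity: slope %.2f, R² %.3f",
                         par_fit$slope, par_fit$r_squared)) +
    theme_minimal()
}
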
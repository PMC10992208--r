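#' Fit a min-max normalizer on a set of runs
#'
#' Records each variable's observed minimum and maximum so values can be
#' rescaled to a target interval (default `[-1, 1]`, the conventional range
#' for a tanh hidden layer) by the affine map
#' \deqn{V' = \frac{V - V_{min}}{V_{max} - V_{min}} (V'_{max} - V'_{min}) + V'_{min}.}
#'
#' Bounds are taken from the supplied data only — fit on the training split
#' so that validation/test values may legitimately map outside the target
#' interval (they are transformed, never clipped).
#'
#' @param runs A data frame of runs.
#' @param variables Character vector of columns to cover; defaults to the
#'   six inputs plus both outputs.
#' @param target_range Length-2 target interval `c(low, high)`.
#' @return A `stover_normalizer`: a tibble with columns `variable`, `v_min`,
#'   `v_max` and a `target` attribute.
#' @export
#' @examples
#' runs <- tibble::tibble(T_C = c(120, 160, 200))
#' fit_normalizer(runs, "T_C")
fit_normalizer <- function(runs, variables = c(input_vars(), output_vars()),
                           target_range = c(-1, 1)) {
  runs <- as_tibble(runs)
  if (length(target_range) != 2 || target_range[1] >= target_range[2]) {
    abort("fit_normalizer: target_range must be c(low, high) with low < high")
  }
  missing <- setdiff(variables, names(runs))
  if (length(missing)) {
    abort(sprintf("fit_normalizer: variable(s) not in data: %s",
                  paste(missing, collapse = ", ")))
  }
  lo <- hi <- numeric(length(variables))
  for (i in seq_along(variables)) {
    x <- runs[[variables[i]]]
    x <- x[is.finite(x)]
    if (length(x) < 2 || min(x) == max(x)) {
      abort(sprintf("fit_normalizer: variable %s has zero range (constant column)",
                    variables[i]))
    }
    lo[i] <- min(x); hi[i] <- max(x)
  }
  out <- tibble(variable = variables, v_min = lo, v_max = hi)
  attr(out, "target") <- as.numeric(target_range)
  class(out) <- c("stover_normalizer", class(out))
  out
}

norm_bounds <- function(spec, variable) {
  i <- match(variable, spec$variable)
  if (is.na(i)) abort(sprintf("normalizer does not cover variable %s", variable))
  c(spec$v_min[i], spec$v_max[i])
}

#' Normalize values of one variable to the target range
#'
#' @param x Numeric vector of values on the original scale.
#' @param variable Variable name covered by `spec`.
#' @param spec A [fit_normalizer()] result.
#' @return Rescaled values; in-range inputs land inside the target interval.
#' @export
#' @examples
#' spec <- fit_normalizer(tibble::tibble(T_C = c(120, 200)), "T_C")
#' normalize_value(c(120, 140, 160, 200), "T_C", spec)
normalize_value <- function(x, variable, spec) {
  b <- norm_bounds(spec, variable)
  tr <- attr(spec, "target")
  (x - b[1]) / (b[2] - b[1]) * (tr[2] - tr[1]) + tr[1]
}

#' Map normalized values back to the original scale
#'
#' Exact inverse of [normalize_value()].
#'
#' @inheritParams normalize_value
#' @export
denormalize_value <- function(x, variable, spec) {
  b <- norm_bounds(spec, variable)
  tr <- attr(spec, "target")
  (x - tr[1]) / (tr[2] - tr[1]) * (b[2] - b[1]) + b[1]
}

#' Normalize every covered column of a run table
#'
#' Columns covered by `spec` and present in `runs` are transformed in place;
#' all other columns pass through untouched.
#'
#' @param runs A data frame of runs.
#' @param spec A [fit_normalizer()] result.
#' @return The transformed tibble.
#' @export
normalize_runs <- function(runs, spec) {
  runs <- as_tibble(runs)
  for (v in intersect(spec$variable, names(runs))) {
    runs[[v]] <- normalize_value(runs[[v]], v, spec)
  }
  runs
}

#' @rdname normalize_runs
#' @export
denormalize_runs <- function(runs, spec) {
  runs <- as_tibble(runs)
  for (v in intersect(spec$variable, names(runs))) {
    runs[[v]] <- denormalize_value(runs[[v]], v, spec)
  }
  runs
}

#' Write / read a normalizer sidecar
#'
#' The per-variable bounds and target range are serialized to JSON so a
#' trained model bundle can reproduce its input scaling exactly.
#'
#' @param spec A `stover_normalizer`.
#' @param path JSON file path.
#' @return `write_normalizer` returns `spec` invisibly; `read_normalizer`
#'   returns the reconstructed `stover_normalizer`.
#' @export
write_normalizer <- function(spec, path) {
  payload <- list(
    target = attr(spec, "target"),
    variables = lapply(seq_len(nrow(spec)), function(i) {
      list(variable = spec$variable[i], v_min = spec$v_min[i], v_max = spec$v_max[i])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(spec)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(payload$variables)
  attr(out, "target") <- as.numeric(payload$target)
  class(out) <- c("stover_normalizer", class(out))
  out
}
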
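#' Design space of the pretreatment/hydrolysis experiment
#'
#' The closed intervals over which the five continuous operating variables
#' were varied, plus the set of allowed acid-kind codes. Defaults are the
#' published design: acid concentration 0.05--0.6 mol/L, temperature
#' 120--200 degrees C, residence time 20--60 min, solid-to-liquid ratio
#' 0.10--0.15 (i.e. 10--15%), enzyme dose 10--20 FPU/g, acids HCl (1),
#' H2SO4 (2) and H3PO4 (3).
#'
#' @param C_IA,T,t,R_SL,E Length-2 numeric `c(low, high)` intervals for the
#'   continuous variables (units as in [input_vars()]).
#' @param acid_codes Integer vector of allowed acid-kind codes.
#' @return A `stover_design_space`: a tibble with columns `variable`, `lower`,
#'   `upper` (one row per continuous variable) and an `acid_codes` attribute.
#' @export
#' @examples
#' design_space()
design_space <- function(C_IA = c(0.05, 0.6), T = c(120, 200), t = c(20, 60),
                         R_SL = c(0.10, 0.15), E = c(10, 20),
                         acid_codes = 1:3) {
  bounds <- list(C_IA_mol_L = C_IA, T_C = T, t_min = t,
                 R_SL_frac = R_SL, E_FPU_g = E)
  for (v in names(bounds)) {
    b <- bounds[[v]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      abort(sprintf("design_space: interval for %s must be c(low, high) with low < high", v))
    }
  }
  out <- tibble(
    variable = names(bounds),
    lower = vapply(bounds, `[`, numeric(1), 1),
    upper = vapply(bounds, `[`, numeric(1), 2)
  )
  attr(out, "acid_codes") <- as.integer(acid_codes)
  class(out) <- c("stover_design_space", class(out))
  out
}

#' Check experimental runs against the design space
#'
#' Flags every condition value lying outside its design interval and every
#' acid-kind code outside the allowed set. Purely a reporting operation:
#' it never errors on out-of-range data.
#'
#' @param runs A data frame of experimental runs (canonical columns, see
#'   [input_vars()]).
#' @param space A [design_space()].
#' @return A tibble of violations with columns `run_id`, `variable`, `value`,
#'   `lower`, `upper` (zero rows when all runs are in range), carrying a
#'   `counts` attribute with per-variable violation counts.
#' @export
#' @examples
#' runs <- tibble::tibble(run_id = "a", k_IA = 2, C_IA_mol_L = 0.7, T_C = 160,
#'                        t_min = 40, R_SL_frac = 0.10, E_FPU_g = 20)
#' validate_ranges(runs)
validate_ranges <- function(runs, space = design_space()) {
  runs <- as_tibble(runs)
  ids <- if ("run_id" %in% names(runs)) as.character(runs$run_id) else
    as.character(seq_len(nrow(runs)))
  rows <- list()
  for (i in seq_len(nrow(space))) {
    v <- space$variable[i]
    if (!v %in% names(runs)) next
    x <- runs[[v]]
    bad <- which(!is.na(x) & (x < space$lower[i] | x > space$upper[i] | !is.finite(x)))
    if (length(bad)) {
      rows[[v]] <- tibble(run_id = ids[bad], variable = v, value = x[bad],
                          lower = space$lower[i], upper = space$upper[i])
    }
  }
  if ("k_IA" %in% names(runs)) {
    codes <- attr(space, "acid_codes")
    x <- runs$k_IA
    bad <- which(!is.na(x) & !(x %in% codes))
    if (length(bad)) {
      rows[["k_IA"]] <- tibble(run_id = ids[bad], variable = "k_IA",
                               value = as.numeric(x[bad]),
                               lower = min(codes), upper = max(codes))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(run_id = character(), variable = character(), value = numeric(),
           lower = numeric(), upper = numeric())
  counts <- table(factor(out$variable, levels = c(input_vars())))
  attr(out, "counts") <- counts
  out
}
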
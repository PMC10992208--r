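# Canonical column names and ordering shared across the package.
#
# The network input order is fixed: acid concentration, temperature, time,
# solid-to-liquid ratio, acid kind, enzyme dose. All weight matrices, the
# importance tables and the serialized formats index inputs in this order.

#' Canonical condition (input) columns, in network input order
#'
#' The six operating variables of the pretreatment/hydrolysis experiment:
#' acid concentration `C_IA` (mol/L), temperature `T` (degrees C), residence
#' time `t` (min), solid-to-liquid ratio `R_SL` (fraction), acid-kind code
#' `k_IA` (1 = HCl, 2 = H2SO4, 3 = H3PO4) and enzyme dose `E` (FPU/g).
#'
#' @return Character vector of the six canonical input column names.
#' @export
#' @examples
#' input_vars()
input_vars <- function() {
  c("C_IA_mol_L", "T_C", "t_min", "R_SL_frac", "k_IA", "E_FPU_g")
}

#' Canonical output columns
#'
#' Glucose concentration `C_Glc` and total phenolic content `C_Phe`, both in
#' g/L of hydrolysate.
#'
#' @return Character vector of the two canonical output column names.
#' @export
output_vars <- function() {
  c("C_Glc_g_L", "C_Phe_g_L")
}

# Short display labels used in reports and figures.
input_labels <- function() {
  c(C_IA_mol_L = "C_IA", T_C = "T", t_min = "t",
    R_SL_frac = "R_SL", k_IA = "k_IA", E_FPU_g = "E")
}

output_labels <- function() {
  c(C_Glc_g_L = "C_Glc", C_Phe_g_L = "C_Phe")
}

canonical_cols <- function() {
  c("run_id", input_vars(), output_vars())
}

# Round half away from zero, the convention used for printed integer percents
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-candidate seed derived from a base seed and an integer tag;
# stays within 32-bit integer range.
derive_seed <- function(base, tag) {
  as.integer((as.numeric(base) + 7919 * as.numeric(tag)) %% 2147483562)
}
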
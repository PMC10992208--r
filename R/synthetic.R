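# Seeded generator of pretreatment/hydrolysis experiments. It emulates the
# qualitative structure reported for the real campaign -- a smooth,
# non-linear response of glucose and phenolics to a latent pretreatment
# severity, the acid ordering H2SO4 > HCl > H3PO4 for glucose release, a
# saturating effect of enzyme dose, and multiplicative measurement noise --
# so the full modelling pipeline can be exercised without the original
# experimental table. It is a statistical stand-in, not a kinetic model.

#' Synthetic response-surface configuration
#'
#' @param space [design_space()] the conditions live in.
#' @param weights Length-4 non-negative weights of the latent severity
#'   terms: acid (concentration x strength), temperature, time and the
#'   (negative) solid-loading term.
#' @param acid_strength Named multipliers for the acid codes 1 (HCl),
#'   2 (H2SO4), 3 (H3PO4); the default ordering 1.2 > 1.0 > 0.7 mirrors the
#'   observed glucose ranking H2SO4 > HCl > H3PO4.
#' @param glucose_range,phenolics_range Calibration spans of the outputs in
#'   g/L; generated values cover (and are clamped to) these intervals,
#'   matching the observed 7.5--25 and 0.8--3.0 g/L.
#' @param K_E Michaelis-type half-saturation of the enzyme-dose factor,
#'   FPU/g.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (truncated at zero).
#' @return A `generator_config` list.
#' @export
generator_config <- function(space = design_space(),
                             weights = c(acid = 0.45, temperature = 0.25,
                                         time = 0.10, solids = 0.20),
                             acid_strength = c(`1` = 1.0, `2` = 1.2, `3` = 0.7),
                             glucose_range = c(7.5, 25),
                             phenolics_range = c(0.8, 3.0),
                             K_E = 5, noise_cv = 0.05) {
  if (length(weights) != 4 || any(weights < 0)) {
    abort("generator_config: weights must be four non-negative numbers")
  }
  if (noise_cv < 0) abort("generator_config: noise_cv must be >= 0")
  if (diff(glucose_range) <= 0 || diff(phenolics_range) <= 0) {
    abort("generator_config: calibration spans must be positive")
  }
  structure(list(space = space, weights = weights,
                 acid_strength = acid_strength,
                 glucose_range = glucose_range,
                 phenolics_range = phenolics_range,
                 K_E = K_E, noise_cv = noise_cv),
            class = "generator_config")
}

#' Space-filling design of operating conditions
#'
#' A seeded Latin-hypercube sample of the five continuous intervals with a
#' uniform random acid-code assignment; every generated row passes
#' [validate_ranges()].
#'
#' @param n_runs Number of runs (>= 1).
#' @param space A [design_space()].
#' @param seed Integer seed.
#' @return A tibble of conditions in the canonical schema (outputs `NA`).
#' @export
#' @examples
#' generate_design(5, seed = 1)
generate_design <- function(n_runs, space = design_space(), seed = 1L) {
  if (n_runs < 1) abort("generate_design: n_runs must be >= 1")
  n_runs <- as.integer(n_runs)
  set.seed(seed)
  U <- lhs::randomLHS(n_runs, nrow(space))
  out <- tibble(run_id = sprintf("syn_%03d", seq_len(n_runs)))
  for (i in seq_len(nrow(space))) {
    out[[space$variable[i]]] <-
      space$lower[i] + U[, i] * (space$upper[i] - space$lower[i])
  }
  out$k_IA <- sample(attr(space, "acid_codes"), n_runs, replace = TRUE)
  out$C_Glc_g_L <- NA_real_
  out$C_Phe_g_L <- NA_real_
  out[canonical_cols()]
}

# Latent pretreatment severity in [s_min, s_max]; each term is min-max
# scaled over the design space so the weights are comparable.
severity <- function(conditions, cfg) {
  sp <- cfg$space
  bound <- function(v) {
    i <- match(v, sp$variable)
    c(sp$lower[i], sp$upper[i])
  }
  z <- function(x, b) (x - b[1]) / (b[2] - b[1])
  p <- cfg$acid_strength[as.character(conditions$k_IA)]
  b_acid <- c(bound("C_IA_mol_L")[1] * min(cfg$acid_strength),
              bound("C_IA_mol_L")[2] * max(cfg$acid_strength))
  w <- cfg$weights
  w[[1]] * z(conditions$C_IA_mol_L * p, b_acid) +
    w[[2]] * z(conditions$T_C, bound("T_C")) +
    w[[3]] * z(conditions$t_min, bound("t_min")) -
    w[[4]] * z(conditions$R_SL_frac, bound("R_SL_frac"))
}

# Noise-free response surface on the g/L scale.
clean_response <- function(conditions, cfg) {
  w <- cfg$weights
  s <- severity(conditions, cfg)
  u <- (s + w[[4]]) / sum(w)              # severity rescaled to [0, 1]
  h <- sqrt(pmax(u, 0))                   # concave saturating ramp
  sp <- cfg$space
  e_hi <- sp$upper[match("E_FPU_g", sp$variable)]
  e_factor <- (conditions$E_FPU_g / (conditions$E_FPU_g + cfg$K_E)) /
    (e_hi / (e_hi + cfg$K_E))
  g <- cfg$glucose_range
  p <- cfg$phenolics_range
  list(glc = g[1] + diff(g) * h * e_factor,
       phe = p[1] + diff(p) * plogis(4 * (s - 0.5)))
}

#' Simulate measured outcomes for a table of conditions
#'
#' Evaluates the latent-severity response surface and adds multiplicative
#' Gaussian noise (CV `cfg$noise_cv`, truncated at zero); outputs are then
#' clamped to the calibration spans so a generated campaign covers exactly
#' the observed concentration ranges. With `replicates > 1` each condition
#' is assayed that many times and the per-condition means are reported
#' (plus `C_Glc_sd_g_L` / `C_Phe_sd_g_L` columns), emulating triplicate
#' wet-lab measurements whose means feed model training.
#'
#' @param conditions Condition table (must lie within `cfg$space`).
#' @param cfg A [generator_config()].
#' @param seed Integer seed; with `noise_cv = 0` the outputs are identical
#'   for any seed.
#' @param replicates Positive integer replicate count.
#' @return `conditions` with `C_Glc_g_L` and `C_Phe_g_L` filled in.
#' @export
simulate_runs <- function(conditions, cfg = generator_config(), seed = 1L,
                          replicates = 1L) {
  conditions <- as_tibble(conditions)
  viol <- validate_ranges(conditions, cfg$space)
  if (nrow(viol) > 0) {
    abort(sprintf("simulate_runs: %d condition value(s) outside the design space (first: %s %s)",
                  nrow(viol), viol$run_id[1], viol$variable[1]))
  }
  clean <- clean_response(conditions, cfg)
  n <- nrow(conditions)
  set.seed(seed)
  noisy <- function(mu, lim) {
    reps <- matrix(mu, nrow = n, ncol = replicates) *
      (1 + matrix(rnorm(n * replicates, sd = cfg$noise_cv), nrow = n))
    reps <- pmin(pmax(reps, 0), lim[2])
    reps <- pmax(reps, lim[1])
    list(mean = rowMeans(reps),
         sd = if (replicates > 1) apply(reps, 1, sd) else NULL)
  }
  g <- noisy(clean$glc, cfg$glucose_range)
  p <- noisy(clean$phe, cfg$phenolics_range)
  conditions$C_Glc_g_L <- g$mean
  conditions$C_Phe_g_L <- p$mean
  if (replicates > 1) {
    conditions$C_Glc_sd_g_L <- g$sd
    conditions$C_Phe_sd_g_L <- p$sd
  }
  conditions
}

#' Simulate one experimental run
#'
#' Single-row convenience wrapper around [simulate_runs()].
#'
#' @param condition A one-row condition table.
#' @inheritParams simulate_runs
#' @return The row with outputs filled in.
#' @export
simulate_experiment <- function(condition, cfg = generator_config(), seed = 1L) {
  simulate_runs(condition, cfg = cfg, seed = seed)
}

#' Generate a complete synthetic campaign
#'
#' [generate_design()] followed by [simulate_runs()] — the drop-in synthetic
#' analogue of the 77-run experimental table.
#'
#' @param n_runs Number of runs (default 77, the size of the real campaign).
#' @inheritParams simulate_runs
#' @return A run table in the canonical schema.
#' @export
#' @examples
#' head(synthetic_runs(10, seed = 1))
synthetic_runs <- function(n_runs = 77, cfg = generator_config(), seed = 1L,
                           replicates = 1L) {
  design <- generate_design(n_runs, cfg$space, seed = seed)
  out <- simulate_runs(design, cfg = cfg, seed = derive_seed(seed, 1),
                       replicates = replicates)
  attr(out, "provenance") <- "synthetic"
  out
}

#' Total phenolics from Folin-Ciocalteu absorbance
#'
#' Converts absorbance at 760 nm to total phenolic content via the
#' gallic-acid standard curve: \eqn{C_{Phe} = (a \cdot A_{760} / V_s) \, N}.
#'
#' @param a Linear coefficient of the gallic-acid standard curve
#'   (g/L per absorbance unit, times mL).
#' @param A760 Absorbance at 760 nm (>= 0).
#' @param V_s Reaction-mixture volume, mL (> 0).
#' @param N Dilution ratio (>= 1).
#' @return Total phenolic content in g/L.
#' @export
#' @examples
#' phenolics_from_absorbance(a = 10, A760 = 0.5, V_s = 10, N = 2)
phenolics_from_absorbance <- function(a, A760, V_s, N = 1) {
  if (any(V_s <= 0)) abort("phenolics_from_absorbance: V_s must be positive")
  if (any(A760 < 0)) abort("phenolics_from_absorbance: A760 must be >= 0")
  if (any(N < 1)) abort("phenolics_from_absorbance: dilution ratio N must be >= 1")
  (a * A760 / V_s) * N
}
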
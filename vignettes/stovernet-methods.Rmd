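---
title: "Modelling corn-stover hydrolysate with a 6-n-2 network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling corn-stover hydrolysate with a 6-n-2 network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stovernet)
```

## The problem and the model

Dilute-acid pretreatment solubilises hemicellulose and loosens lignin so
that cellulases can reach cellulose; the same chemistry releases phenolic
lignin fragments that inhibit the downstream enzymes and fermentation. A
campaign over six operating variables — acid concentration $C_{IA}$
(0.05–0.6 mol/L), temperature $T$ (120–200 °C), residence time $t$
(20–60 min), solid-to-liquid ratio $R_{SL}$ (0.10–0.15), acid kind
$k_{IA} \in \{1,2,3\}$ for HCl/H$_2$SO$_4$/H$_3$PO$_4$, and enzyme dose $E$
(10–20 FPU/g) — measures glucose $C_{Glc}$ and total phenolics $C_{Phe}$ in
the final hydrolysate.

`stovernet` models both outputs jointly with one single-hidden-layer
feedforward network,

$$\hat y_k = b_{2,k} + \sum_{j=1}^{n} LW_{k,j}\,
  \tanh\!\Big(b_{1,j} + \sum_{i=1}^{6} IW_{j,i}\, x_i\Big),$$

with all variables min–max scaled to $[-1,1]$. The activation pairing
(tanh hidden, identity output) is the conventional one for that scaling;
both are configurable, and nothing downstream depends on the choice: the
Garson importance statistic uses only the weight magnitudes.

### Normalization

$V' = \frac{V - V_{\min}}{V_{\max} - V_{\min}}(V'_{\max} - V'_{\min}) +
V'_{\min}$, inverted exactly for reporting. Bounds are fitted on the
**training split only**, so validation/test values can map slightly outside
$[-1,1]$; they are transformed, never clipped — the standard way to avoid
information leaking from held-out data into the scaling. Targets are
normalized too by default (`normalize_targets`): with g/L-scale targets
this only improves optimization conditioning, and every reported RMSE is
computed after denormalization, on the original g/L scale.

### Training protocol

Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) on mini-batches of 2, with the mean squared error of
both normalized outputs weighted equally. One *iteration* is one full epoch
over the reshuffled training set; with 57 training runs and batch size 2
the final short batch is kept. 800 iterations is the default because the
validation RMSE trajectory plateaus there in the iteration sweep. Weights
initialise from a seeded uniform $(-0.5, 0.5)$, biases at zero; a run is a
pure function of (data, config, seed), which the determinism tests assert
byte-for-byte.

### Architecture search

Candidate hidden sizes come from the empirical rule $n = \sqrt{i+k} +
\alpha$ with $\alpha = 1 \dots 10$. Because $\sqrt{8} + \alpha$ is not an
integer, the window is realised as floor at the lower end and round-half-up
at the upper end, giving the 11 candidates 3–13 for the 6-input, 2-output
case; an explicit candidate list can override the rule. Each candidate
trains independently for 500 epochs from its own seed, derived
deterministically from (base seed, $n$) so the sweep is invariant to
evaluation order. Selection formalises the informal "combination analysis"
of the two RMSE columns as the sum over outputs of validation RMSE divided
by that output's observed range — a scale-free way to combine a
~17 g/L-range output with a ~2 g/L-range one — with ties broken toward the
smaller network.

### Split convention

75:15:10 with a seeded uniform shuffle. Only the training count (57 of 77)
is pinned by floor(0.75·N); the remainder is divided in 15:10 proportion
with the validation share rounded, giving 57/12/8 at $N = 77$. No
stratification by acid kind is attempted. The 12/8 division is this
package's convention; only the 57 is externally fixed.

## The Garson statistic

For output $k$,
$$I_i = \frac{\sum_j \big(|IW_{j,i}| / \sum_{i'} |IW_{j,i'}|\big)\,|LW_{k,j}|}
             {\sum_{i''}\sum_j \big(|IW_{j,i''}| / \sum_{i'} |IW_{j,i'}|\big)\,|LW_{k,j}|}.$$
Biases are excluded (the statistic is defined on the connection weights
only) and importance is computed per output — no cross-output aggregate is
defined. Reported integer percents use round-half-up, matching how such
tables are conventionally printed, and are *not* forced to sum to 100;
unrounded fractions are always carried alongside. Applied to the bundled
published weight table the statistic puts $C_{IA}$ first on both outputs
(23% / 22%) with the five pretreatment variables carrying 79% of the
glucose importance:

```{r}
importance_report(load_table3_weights())
```

## The synthetic generator

The generator stands in for the original 77-run experimental table; it
emulates the *structure* the analysis assumes, not the chemistry. A latent
pretreatment severity

$$s = w_1\, z(C_{IA}\, p(k_{IA})) + w_2\, z(T) + w_3\, z(t) - w_4\, z(R_{SL}),$$

with min–max scalings $z(\cdot)$ over the design space, acid-strength
multipliers $p = (1.0, 1.2, 0.7)$ reproducing the observed glucose ordering
H$_2$SO$_4$ > HCl > H$_3$PO$_4$, and weights $w = (0.45, 0.25, 0.10,
0.20)$, drives both outputs: glucose through a concave ramp
$\sqrt{\cdot}$ in rescaled severity times a Michaelis-type enzyme factor
$E/(E + K_E)$ with $K_E = 5$ FPU/g, phenolics through a logistic
$\sigma(4(s - 0.5))$. Multiplicative Gaussian noise (CV 0.05 by default,
truncated at zero) models assay error; supporting triplicate replicates
whose means feed training mirrors how such campaigns are measured. Outputs
are calibrated — and, after noise, clamped — to the observed spans
7.5–25 g/L (glucose) and 0.8–3.0 g/L (phenolics), so a generated campaign
covers exactly the concentration ranges the model is meant to operate in;
the clamp touches only the extreme tails at the default noise level.
Designs are Latin-hypercube samples of the five continuous intervals with
uniform acid codes, so every generated row is in-range by construction.
The Folin–Ciocalteu forward model
$C_{Phe} = (a\,A_{760}/V_s)\,N$ is included so assay-level inputs can be
converted to concentrations.

What passing tests on this generator do **not** show: real campaigns are
not space-filling (the original design was structured), real noise is not
exactly multiplicative-Gaussian, and real pretreatment chemistry has
interactions (e.g. severity-dependent phenolic degradation) the surface
omits. Conclusions about *pipeline correctness* transfer; conclusions about
*biology* do not.

## Numerical choices

- RMSE uses squared residuals, $\sqrt{\tfrac1m \sum (y_{pre} -
  \hat y_{exp})^2}$; it is reported on the denormalized g/L scale
  everywhere.
- Parity evaluation regresses predictions on measurements with an
  intercept; $R^2$ is computed directly from the residual and total sums of
  squares (avoiding the perfect-fit warning of `summary.lm`).
- Gradients are analytic backpropagation, verified against central finite
  differences to relative error $<10^{-5}$; the forward pass and the
  Garson statistic are verified against explicit nested-loop oracles to
  $10^{-12}$.
- Degenerate inputs fail loudly: constant columns in the normalizer, empty
  datasets or all-zero split ratios, hidden rows with all-zero input
  weights in the Garson denominator, dimension mismatches in weight tables.
- All derived seeds stay within 32-bit integer range.

## Problem sizes used in the checks

Module tests run seconds-scale configurations (24–40 runs, tens of epochs);
the end-to-end scientific checks train full 6-12-2 models for 800 epochs on
77-run campaigns, ten seeds' worth, which completes in about a minute on a
single core. These sizes were chosen as the smallest that exercise every
contract at the study's own scale.

## A known limitation of Garson recovery, found with this generator

One property we probed deserves honest reporting. On noisy 77-run
campaigns (CV 0.02) the generator's functionally dominant input is
unambiguous: a one-at-a-time sensitivity of the noiseless surface gives
$C_{IA}$ a 34–39% share of the output swing, about 1.8× the runner-up,
while $k_{IA}$ holds only ~9%. Yet the Garson ranking of networks trained
under the standard protocol places $C_{IA}$ first for glucose in only
about 4 of 10 seeds, frequently promoting $k_{IA}$ instead. The mechanism
is visible in the weights: the acid-strength map is non-monotone in the
ordinal code (code 2 strongest, code 3 weakest), so the network must spend
large hidden-layer weights carving a dip in a 3-level input — and Garson
rewards weight magnitude, not effect size. A monotone recoding reduces but
does not remove the effect. The corresponding acceptance property is left
failing rather than weakened, because it documents a real fidelity limit
of connection-weight importance for discrete inputs with non-monotone
effects; the in-paper worked example (fixed published weights) is
unaffected, as are the parity properties. Practitioners comparing Garson
output across retrained networks should expect this instability and
corroborate rankings with a model-free sensitivity measure.
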
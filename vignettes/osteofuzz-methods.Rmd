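---
title: "Modelling MSC osteogenic differentiation with a fuzzy-logic controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MSC osteogenic differentiation with a fuzzy-logic controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteofuzz)
```

## The model

`osteofuzz` simulates the osteogenic differentiation of a mesenchymal stem
cell (MSC) as a two-phase process driven by five extracellular signals:
the Mg²⁺ concentration [mM] and the inflammatory cytokines TNF-α, IL-10,
IL-8 and IL-1β [ng/ml]. The pipeline has three stages.

**1. Mamdani controller.** Each signal is a linguistic variable with
triangular/trapezoidal membership levels. Cytokine axes are fuzzified on a
log₁₀ scale because their biologically anchored doses span four decades
(0.01–100 ng/ml); Mg²⁺ uses a linear axis. The rule base encodes the
dose-dependent biology: Mg²⁺ is physiological at 0.8 mM, inhibitory for
early differentiation below it, stimulatory in the 2–10 mM window (peak
`p_ms`), inhibitory for the late phase above 1.8 mM and destructive above
20 mM; TNF-α is stimulatory at 1 ng/ml, neutral at 10 and inhibitory at
100; IL-8 is increasingly stimulatory up to 100 ng/ml; IL-1β stimulates at
low doses but antagonizes the IL-8 response (encoded by gating the
Extremely-fast rule on IL-1β being Negligible). IL-10 carries two
membership sets selected by cumulative exposure: up to 48 h its stimulatory
degree rises steadily from 0 to 10 ng/ml; beyond 48 h the response peaks at
0.1 ng/ml and 10 ng/ml or more is inhibitory. Inference is standard
Mamdani semantics — min for AND and implication, max for aggregation,
`1 − μ` for NOT — with centroid defuzzification of Gaussian output levels
(activation 1, σ = 0.05) on [0, 1]. The crisp outputs `f_e`, `f_l` are the
fuzzy early/late rates; 0.5 is the physiological rate.

**2. Maturity dynamics.** Rates are scaled around the physiological point,
`S(x) = 1 + 2α(x − 0.5)` with the stimulatory coefficient on the
`x > 0.5` branch and the inhibitory one below, clamped at 0 (a
differentiation rate cannot be negative), and multiplied by
`r₀ = 1/T_d`. Maturity accumulates `r_e` until the early phase ends at
`T_e = M_t · T_d` and `r_l` afterwards, clamped to [0, 1].

**3. Marker read-out.** `y_i = (x + β_i)^{n_i} · k_{i,j}`: the early marker
ALP tracks maturity only up to `M_t` and plateaus (x = min(maturity,
M_t)); the late markers OC and ARS track maturity throughout. `β_i` is the
detectable baseline at maturity zero, `n_i` the degree of nonlinearity and
`k_{i,j}` a per-study correction factor absorbing unit differences.

## Parameters, units, defaults

The registry has exactly 30 free entries (`model_parameters()`,
`parameter_priors()`). Defaults were fixed once from the textual anchors
of the underlying biology, not fitted:

| group | entries | default | why |
|---|---|---|---|
| Mg anchors | `p_ms`, `p_md` [mM] | 6, 15 | stimulatory window 2–10 mM with strongest reported effect at 6–8 mM; inhibition onset between 10 and 20 mM |
| cytokine anchors | `p_8f`, `p_1bs`, `p_1bie` [ng/ml] | 10, 5, 50 | IL-8 intermediate optimum inside 0–100; IL-1β stimulatory within 1–10 |
| output centers | `p_es/p_ls`, `p_ef/p_lf`, `p_evf` | 0.3, 0.7, 0.85 | symmetric around the physiological 0.5; ordering constraints enforced |
| dynamics | `M_t`, `T_d` [d] | 0.5, 21 | three-week osteogenic differentiation assay; day-21 OC/ARS endpoints |
| sensitivities | four `α` | 0.5 | mid-prior; `S(x)` then spans 0.5–1.5 |
| markers | `β`, `n`, eight `k` | 0.5, 1, 1 | detectable baseline; near-linear maturity–marker relation; unit-free default |

The early-differentiation output variable carries six levels; the
"Arrested" level (center 0.05) is never referenced by a rule and only
completes the level count, and the Extremely-fast center (0.95) and the
fifth late-differentiation level (0.85) are fixed, not calibratable.

## Numerical choices

* Centroid grid: 1001 uniform points on [0, 1] — ≥ 50 points per output
  standard deviation (σ = 0.05). Tests check agreement with a 10⁵-point
  trapezoid oracle to 10⁻³.
* Out-of-domain inputs are clamped to the domain boundary (concentrations
  beyond the last anchor behave as the extreme level); a zero cytokine
  concentration maps to the lower end of the log axis. Strict domain
  checking is available per variable (`clamp = FALSE`).
* Integration: forward Euler with `dt = 1 h` over piecewise-constant
  schedules. Because rates are constant within segments, the Euler
  trajectory is exact whenever segment boundaries and `T_e` fall on grid
  points; `simulate_study()` therefore uses the equivalent segment-sum
  closed form, and the equality is tested. After a treatment pulse,
  signals revert to baseline (Mg 0.8 mM, cytokines 0).
* Zero total rule activation raises a defined error; the shipped rule base
  covers every non-negative input state (tested by grid sweep).
* A rule base row with alternatives ("any of") is expanded into one rule
  per alternative, which under min/max semantics equals an OR within the
  slot.

## Design choices where the design was open

* **t-norms.** Only "Mamdani-type" and "centroid" are fixed by the model
  family; min/max/complement are the standard completion and are what this
  package implements (Sugeno inference and other defuzzifiers are out of
  scope).
* **Scaling branches.** The stimulatory coefficient is attached to the
  `x > 0.5` branch: a larger `alpha_es` must speed maturation under
  stimulatory signals (this is also asserted by a test). The transposed
  reading is available via `swap_branches = TRUE`.
* **Phase switching.** The early phase ends at the *time* `T_e = M_t·T_d`
  by default, even when rates are non-physiological; maturity-based
  switching (early phase ends when maturity reaches `M_t`, consistent with
  the ALP plateau rule) is available via `switch_on = "maturity"` for
  exploration.
* **Fitness.** The per-item score is `max(0, 1 − |E−S|/E)` so that 1 is a
  perfect fit; the raw discrepancy `|E−S|/E` is available via
  `raw = TRUE`.
* **DE settings.** DE/rand/1/bin with F = 0.8, CR = 0.9 — the classic
  robust defaults — population 15 and 200 generations; log-scale priors
  (the `k` factors) are searched in log₁₀ space. Run `i` of a repeated
  calibration uses seed `base_seed + i − 1` and every run is recorded with
  its seed.
* **Half-split convergence.** The repetition count is declared sufficient
  when each parameter's first-half and second-half means differ by at most
  5 % (default) of its prior length.
* **Sensitivity.** LSSP perturbs each study's relevant parameter subset by
  ±50 % along a resolution-IV two-level fractional factorial (main effects
  unconfounded with two-factor interactions; resolution III available) and
  ranks parameters by the mean absolute ANOVA main effect on per-item
  outputs normalized by their across-run means (hence invariant to output
  rescaling); mean fitness is an auxiliary response when data are given.
  SSIP perturbs one parameter at a time by ±15 % and reports per-item
  percentage changes and the sd across the ± pair. Perturbed values
  escaping the prior bounds are clipped.

## The synthetic-measurement generator

The five calibration experiments published their measurements only as
figure bars, so the package ships their *designs* (conditions, treatment
schedules, measurement days, normalization) and a generator
(`generate_synthetic()`) that simulates them under a chosen registry and
applies multiplicative lognormal noise with mean 1 and a coefficient of
variation of 0.1 by default — a typical between-replicate spread for
colorimetric ALP/ARS assays. An additive error model can be emulated by
supplying a user CSV. What the generator emulates: the study structure,
fold-over-control reporting (study 4), 48-h cytokine pulses (studies 3–4)
and proportional measurement noise. What it does not emulate: donor and
culture-medium variability between laboratories, systematic inter-study
biases beyond the `k` factors, and cell-population heterogeneity.
Passing parameter-recovery tests therefore show self-consistency of the
estimation machinery — that the protocol recovers parameters when the
model is true — not fidelity to any particular laboratory's cells.

## Problem sizes used by the shipped checks

The test suite runs the full recovery protocol at the scale of a
single-study analysis: 20 repeated DE runs (population 15, 200
generations) calibrating {`M_t`, `T_d`, `alpha_es`} on noise-free
synthetic data over all five designs, plus miniature 2–4-run calibrations
for the bookkeeping paths. The centroid oracle uses 100 random activation
patterns against a 10⁵-point grid; noise-model statistics use 300
generator draws.

## Known limitations

* Interactions between signals other than the IL-8/IL-1β antagonism are
  not encoded — the literature the rule base rests on reports none.
* The model describes the average cell; population heterogeneity,
  proliferation and spatial/agent-based extensions are out of scope, as
  are substrate stiffness and the TGF-β/BMP axis.
* Membership breakpoints between the named anchors are qualitative
  choices; all of them live in `build_*_variable()` so they can be re-fit
  if quantitative dose–response curves become available.
* With `n_runs` in the low tens the half-split check can flag convergence
  for objectives with a single basin; establishing stable posteriors for
  the full 30-parameter registry takes repetition counts in the hundreds.
  The check's tolerance is configurable.
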
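---
title: "Biphasic dose-response analysis of multi-driver cancer cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic dose-response analysis of multi-driver cancer cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasr)
library(dplyr)
```

## The problem and the models

Targeted cancer drugs are conventionally profiled with the three-parameter
Hill equation,

$$I(D) = I_{max} \frac{D^n}{IC_{50}^{*n} + D^n},$$

where $I$ is the inhibition of cell viability, $D$ the drug concentration,
$I_{max}$ the maximal inhibition, $IC_{50}^*$ the half-effect concentration
of the drug-sensitive fraction of viability, and $n$ the Hill coefficient.
Kinase-inhibitor response curves of many cancer cell lines are conspicuously
shallow ($n < 1$), which under the Hill reading requires a negative
cooperativity with no mechanistic basis.

The biphasic model instead reads a shallow curve as the superposition of two
saturable one-site effects: a high-affinity, target-specific phase and a
low-affinity, off-target phase,

$$I(D) = F_1 \frac{D}{D + K_{d1}} + F_2 \frac{D}{D + K_{d2}},
\qquad F_2 = 1 - F_1 .$$

$F_1$ is the fraction of viability that depends on the drug's nominal
target (its "driver share"), $K_{d1}$ the apparent dissociation constant of
that interaction, and ($F_2$, $K_{d2}$) collect everything else the drug
does at higher concentrations. $F_2$ is always derived from $F_1$, never a
free parameter. A cell whose viability collapses through a single target
(a *mono-driver* cell) shows $F_1 \approx 100\%$ and needs no second phase;
a *multi-driver* cell shows a partial $F_1$, because blocking one driver
leaves the others running.

Both models are implemented as closed forms (`hill_inhibition()`,
`biphasic_inhibition()`) with exact inverses (`inverse_dose()`: analytic for
Hill, bracketed root-finding at 1e-9 relative tolerance for the biphasic
form). Internally every response is an inhibition *fraction* and every
concentration is in *nM*; percentages and µM appear only at reporting
boundaries.

## Fitting

`fit_hill()` and `fit_biphasic()` minimize the unweighted root-mean-square
error (RMSE) between observed and predicted inhibition — the same objective
a spreadsheet-solver workflow uses, which keeps fitted values comparable
with the published parameter tables this package is validated against.
Options and their defaults:

* **Aggregation.** The objective is evaluated on per-concentration mean
  inhibition (the curve a screening figure plots). `use_replicates = TRUE`
  fits all replicate wells jointly instead; both routes see the same truth
  and the default mirrors the one-curve-per-drug convention.
* **Bounds.** $I_{max}, F_1 \in [0, 1]$; $K_d$'s and $IC_{50}^*$ in
  $[0.1\ \mathrm{nM}, 100\ \mu M]$ on a log10 scale; $n \in [0.1, 5]$;
  $K_{d2} \ge K_{d1}$ by construction (phase 1 is the high-affinity phase,
  which removes label switching). The 100 µM upper bound is ~5× the top
  assay dose of the standard dilution series; beyond it a constant is not
  identifiable, and a $K_{d2}$ landing on the bound is reported censored
  (">100 µM").
* **Multi-start.** Bounded quasi-Newton (L-BFGS-B) from a fixed grid of
  starts (12 for Hill: log-spaced $IC_{50}^*$ × $n \in \{0.5, 1, 2\}$; 18
  for the biphasic model over $F_1$ × $\log K_{d1}$ × phase separation).
  The grid is fixed, so fitting is deterministic for identical input. Tests
  verify the optimizer never loses to a dense 40×40×40 grid-search oracle
  by more than 1e-4 RMSE.
* **Single-phase collapse.** After the two-phase fit, the curve is refit
  with $F_1$ fixed at 1. If that single-phase fit is within 10% of the
  two-phase RMSE — or the free fit already puts $F_1 \ge 0.995$ — the
  monophasic model is reported ($F_1 = 100\%$, $K_{d2}$ "None"). This
  parsimony rule is needed because on truly monophasic data the free second
  phase otherwise absorbs replicate noise (fitted $F_1 \approx 0.98$ with a
  spurious, tiny second phase), while on genuinely biphasic data the
  single-phase refit is several-fold worse and never triggers. The 10% band
  matches the RMSE-comparability band used in `compare_models()`.

`compare_models()` reports both RMSEs and their ratio, and declares the
models "comparable" within a 10% band — biphasic fits are preferred on
evidence, not by default.

## Driver classification

`classify_response()` operationalizes the joint Hill + biphasic signature:

| criterion | mono-driver | multi-driver |
|---|---|---|
| target-specific fraction | $F_1 \ge$ `f1_hi` (0.85) | $F_1 \le$ `f1_lo` (0.80) |
| Hill coefficient | $n \ge$ `n_hi` (0.9) | $n \le$ `n_lo` (0.85) |
| potency ratio $IC_{50}^*/K_{d1}$ | $\le$ `r_lo` (1.1) | $\ge$ `r_hi` (1.1) |

A verdict requires **all three** criteria of its pattern; anything else is
indeterminate. The published criteria are qualitative, so the numeric
defaults were calibrated once against the 25 published panel responses
shipped in `inst/extdata/` (18 reference-panel rows spanning mono- and
multi-driver cell lines, plus 7 DU-4475 rows): in those tables mono-pattern
potency ratios never exceed 1.04 while multi-pattern ratios start at 1.14,
mono $F_1$ bottoms out at 86%, and multi-pattern $n$ tops out at 0.69.
`n_hi` is 0.9 rather than 1.0 because a noisy one-site curve fits $n$
jittered symmetrically around 1; at `n_hi = 1.0` half of all true
mono-driver replicate screens would be refused. Every threshold is a
`driver_thresholds()` argument and is echoed per row in the output.

`classify_cell_line()` aggregates: one mono-pattern response makes the cell
mono-driver (one blocked target sufficed for full inhibition); multi-driver
status needs at least two multi-pattern responses against *distinct*
declared targets. Target annotations are an explicit input — they come from
external binding data, never from the curves.

## Synergy analysis

For a 1:1 (equal molar per-drug) combination, `ic_x()` reads the dose at an
inhibition level by linear interpolation on the log10-dose scale between the
first bracketing grid points, with means clamped to [0, 1] at this boundary
only (fitting sees unclamped values, because clamping before fitting biases
low-dose estimates). A level above the curve's plateau is *unattainable*
and propagates as an explicit flag rather than a number. A model-based
route (`method = "model_based"`, via `inverse_dose()`) is available as a
cross-check; the two agree within one two-fold grid step on smooth curves.

`dose_reduction_index()` implements
$DRI = IC_{x,1} \cdot IC_{x,2} / (IC_{x,1+2} (IC_{x,1} + IC_{x,2}))$,
the reciprocal of the Chou–Talalay combination index
$CI = IC_{x,1+2}/IC_{x,1} + IC_{x,1+2}/IC_{x,2}$ for a 1:1 mixture
($DRI \cdot CI = 1$ exactly, property-tested). Because the pooled DRI folds
both drugs into one number, `synergy_report()` also reports the per-drug
dose reductions $IC_{x,i}/IC_{x,1+2}$. Any required $IC_x$ being
unattainable makes the DRI absent with a reason — the honest reading of a
partial inhibitor that never reaches the level.

`isobologram_points()` returns the additivity line between the single-agent
intercepts, the combination point, and the interaction index
$d_1/IC_{x,1} + d_2/IC_{x,2}$ (< 1 synergy). `rank_combinations()` scores
candidate pairs by combined driver coverage $\min(F_{1,a} + F_{1,b}, 1)$,
ties broken by the weaker $K_{d1}$ — the design logic that pairs drugs
covering complementary drivers. `specificity_fold()` compares $IC_x$
between cell lines and propagates censoring as a lower bound.

## The synthetic-data generator

No raw screening wells are redistributed with the package, so all pipeline
tests run on synthetic plates that emulate the study design:

* 16 two-fold dilutions from 0.6 nM (top ≈ 19.66 µM): the unique standard
  series matching a "0.6 nM to 20 µM, 16 points" window;
* triplicate wells, i.i.d. Gaussian noise with sd 0.02 *on the inhibition
  scale* — bracketing the 0.018–0.11 RMSE range of the published fits;
* `simulate_plate()` emits raw A490/A750 wells (controls at exact baseline)
  that normalize back to the identical inhibition matrix under the same
  seed, exercising the normalization path end to end.

For combinations, two generative truths are provided.
`"independent_drivers"` multiplies survival across all phases of both
drugs, $V(D) = \prod_k (1 - f_k D/(D + K_k))$ — an independence assumption
we chose for simulation; the study asserts that distinct-driver effects
combine but states no formula, so this truth is never compared against
published numbers. `"loewe_additive"` constructs the no-interaction null by
dose equivalence (solving $D/D_1(I) + D/D_2(I) = 1$ per dose), and lands on
the isobologram additivity line within interpolation tolerance — the
calibration check for the synergy machinery.

What the generator does *not* emulate: plate-layout artifacts and edge
effects, per-plate (as opposed to per-well) noise correlation,
growth-kinetic or cell-cycle effects, and any mechanistic signaling.
Passing recovery tests therefore demonstrate the *estimator* works under
the stated noise model, not that real screens are free of structured error.

## Numerical choices and degenerate inputs

* Fits require ≥ 5 distinct positive concentrations; fewer is an error,
  not a silent fit.
* All-starts optimizer failure returns `converged = FALSE` with the best
  found parameters; classification then refuses a verdict.
* When phases merge ($K_{d2}/K_{d1} < 10$) the two-site decomposition is
  not reliably identifiable; recovery tests use published sets with ≥ 45×
  separation, and the censoring bound absorbs the unidentifiable tail.
* `ic_x()` uses the first crossing and warns when replicate noise makes a
  mean curve cross a level more than once.
* Problem sizes throughout the tests (16-point curves, 3 replicates, 20
  seeds per recovery scenario, 40³ oracle grids) were chosen as the
  smallest designs that exercise the full pipeline at the study's own
  dimensions.

## Worked pipeline

```{r}
truth <- biphasic_params(0.49, 29.9, 9300)
wells <- simulate_plate(truth, noise_sd = 0.02, seed = 1,
                        cell_line = "TNBC-1", treatment = "dasatinib")
curve <- normalize_plate(wells)
hill <- fit_hill(curve)
bip <- fit_biphasic(curve)
hill
bip
compare_models(hill, bip)
classify_response(hill, bip)[, c("verdict", "f1", "hill_n", "potency_ratio")]
```

## Known limitations

Point estimates only — no bootstrap or profile intervals on fitted
parameters, mirroring the source workflow. No three-or-more-phase models.
No response-surface synergy models (Loewe/Bliss surfaces) beyond the
additivity line; the analysis is $IC_x$-level by design. GDSC-style input
support covers the normalization computation, not bulk database retrieval.
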
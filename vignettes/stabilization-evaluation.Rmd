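---
title: "Evaluating soil heavy-metal stabilization with stabeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating soil heavy-metal stabilization with stabeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabeval)
```

## The evaluation problem

In-situ stabilization reduces the *available* (bioavailable, extractable)
fraction of heavy metals in farmland soil by applying amendments; the total
metal stays in place. Whether a treatment "worked" is therefore a
multi-criteria question: the available metal should fall, but the field must
also remain (or become) arable — fertility, crop growth, food safety and the
amendment's own properties all matter, and no single regulatory threshold
covers the available fraction. `stabeval` operationalizes this as a weighted
composite index over 16 indicators in three branches:

* **soil** — pH, organic matter (SOM), cation exchange capacity (CEC),
  available N/P/K, available heavy metal (AHM), total heavy metal (THM);
* **crop** — biomass, production, heavy metal in the edible, above-ground
  and root parts;
* **amendment** — cost, heavy metal content, stability (effect lifetime).

Indicators fall into three evaluation groups: **I** — governed by a national
standard (THM, edible-part metal, amendment metal; these carry a hard
compliance flag), **II** — gradable under farmland classification management
(pH, SOM, CEC, N/P/K, biomass, production, cost), and **III** — dynamic
quantities without an external criterion (AHM, crop uptake, stability),
evaluated through derived statistics with conventions from prior practice.

## Weights: analytic hierarchy process

Sibling elements under each node of the target → criterion → sub-criterion
→ indicator tree are compared pairwise on the Saaty 1–9 scale, giving a
positive reciprocal judgment matrix $P = (b_{ij})$. The priority vector is
computed by the sum-product method:

$$\hat b_{ij} = \frac{b_{ij}}{\sum_i b_{ij}}, \qquad
  \bar W_i = \sum_j \hat b_{ij}, \qquad
  W_i = \frac{\bar W_i}{\sum_i \bar W_i},$$

with the principal eigenvalue estimated as
$\lambda_{\max} = \frac{1}{n}\sum_i \frac{(PW)_i}{W_i}$. The sum-product
method is the normative implementation here; the test suite checks it
against a dense eigen-decomposition oracle and finds component-wise
agreement better than 0.02 on matrices whose log-ratio perturbation from
consistency has standard deviation up to 0.3 — the regime questionnaire
data plausibly occupies. Consistency is accepted when
$CR = CI/RI < 0.1$, where $CI = (\lambda_{\max} - n)/(n - 1)$ and $RI$ is
the tabulated random index for $n \le 9$. Two edge conventions are fixed
deliberately:

* $n \le 2$: reciprocal matrices of order 2 are always consistent and
  $RI = 0$; $CR$ is defined as 0 and the matrix passes, rather than
  dividing by zero.
* $n > 9$: no $RI$ value is tabulated; this is a hard error, not an
  extrapolation.

Expert panels are aggregated as the equal-weight arithmetic mean of the
per-expert **priority vectors** (not matrix entries), after excluding
matrices with $CR \ge 0.1$. Vector aggregation preserves the sum-to-one
contract trivially and keeps each expert's internal consistency filter
independent; per-expert weights are accepted, and a weighted geometric mean
of the matrices (which preserves reciprocity) is available via
`aggregate_experts(method = "geometric_matrix")` for users who prefer
aggregating judgments rather than conclusions.

The packaged hierarchy (`default_hierarchy()`) carries the expert-derived
weights: soil 0.544 (fertility 0.295 / heavy metal 0.705), crop 0.316
(growth 0.265 / pollution accumulation 0.735), amendment 0.140. The leaf
comprehensive weights were published after independent rounding to three
decimals, so they sum to 1.003 and are not exactly the product of the
printed branch weights (e.g. the fertility leaves sum to 0.155 while
0.544 × 0.295 = 0.1605). The package therefore exposes both readings:
`default_weights("printed")` returns the published values verbatim (the
default, and what reproduces the published worked example), and
`default_weights("renormalized")` divides by the sum so the weights are a
proper probability vector. `compose_weights()` rebuilds comprehensive
weights from within-parent-renormalized locals; on the packaged tree it
agrees with the printed values to better than 0.01, which is the expected
size of the rounding artefact.

## Transforms and response curves

Three derived statistics convert raw measurements into scoreable values:

* **Bio-accumulation factor** $BAF = 100\,[X]_{crop}/[X]_{soil}$ (%),
  classed very weak ($\le 1$%), weak (1–10%], moderate (10–100%], strong
  (> 100%). The soil denominator is always taken from the input
  (`soil_total_hm`), never recomputed: in the packaged pot experiment it is
  the 5 mg/kg Cd spike, the only denominator that reproduces the published
  root scores (0.60/0.68/0.71), not spike + 0.18 mg/kg background.
* **Reduction rate** $\alpha = 100\,(X_b - X_a)/X_b$ (%) of the available
  metal, graded equidistantly: poor [0, 25), medium [25, 50), good
  [50, 75), excellent [75, 100]. A negative $\alpha$ (available metal
  increased) is legal data: it is returned with a warning and scores 0
  downstream rather than erroring, since a failed treatment is a result,
  not a malfunction.
* **Reference ratios** for production, biomass and cost (actual over
  average local production, crop weight over average local crop weight,
  cost over crop revenue). References are mandatory configuration, never
  estimated from the data at hand.

Scores come from three piecewise-linear membership curves, chosen per
indicator in the registry:

| curve | shape | used for |
|---|---|---|
| S-type | 0 below `L`, ramp to 1 at `H` | SOM, CEC, A-N, A-P, A-K, production, biomass, stability, AHM (on α) |
| inverse-S | 1 below `L`, ramp to 0 at `H` | THM, edible/above-ground/root metal (on BAF), amendment metal, cost |
| parabolic | 0 at `L1`, plateau 1 on `[L, H]`, 0 at `H1` | pH |

Piecewise-linear forms are used deliberately: they are the simplified
response model that the published worked example was scored with, and
smooth sigmoid variants would not reproduce it. Two curve-definition
corrections were required to make the system self-consistent:

* The parabolic **rising limb** is $(x - L_1)/(L - L_1)$. The published
  formula table prints $x/L_1$, which exceeds 1 (pH 4 would score 1.33) and
  is discontinuous at $L_1$; the corrected limb is the standard trapezoidal
  membership, matches the plotted curve shape, and reproduces every
  published pH score.
* **AHM is scored on a rising ramp in α** with `H = 75%` (the "excellent"
  grade boundary), although the published table groups it with the
  inverse-S indicators. Every published AHM score *rises* with the
  reduction rate (α = 0 → 0, 24.9% → 0.33, 47.4% → 0.63 = α/75); the
  direction in the table is taken as a labelling slip, since a larger
  reduction is unambiguously better.

Default thresholds (Cd where metal-specific) live in the packaged registry
and merge with user overrides by indicator name; `L` defaults to 0 where
the grading tables leave it blank. One registry default knowingly departs
from the published threshold table: **biomass** uses `L = 0, H = 1`, i.e.
the score is the reference ratio itself capped at 1. The published
threshold table lists `H = 0.8`, but the published worked-example scores
(0.91, 0.99, 1 for ratios 0.913, 0.992, 1.307 against the back-computed
1.27 g reference) are the ratios, not a ramp saturating at 0.8. The
registry entry records the 1.27 g reference with `assumption: true`, since
the underlying local average was not published.

Boundary conventions, where interval notation in the source material is
mixed: BAF classes are upper-closed, α grades lower-closed, composite
grades upper-closed. Stability readings reported as "beyond the observation
window" (`>3` years) parse as just above the bound and score 1 against the
3-year life-cycle criterion.

## Composite score, grade and verdict

The composite score is $S_i = \sum_i \omega_i X_i$ over the scored
indicators. Indicators with a weight but no measurement contribute 0 and
are listed in the result's `missing` field; the weights are **not**
renormalized over the measured subset by default. This is a real modelling
choice: the unrenormalized sum scores a treatment against the *full*
evaluation system (unmeasured aspects earn nothing), and it is the
convention under which the packaged worked example reproduces the published
composites. `renormalize_missing = TRUE` rescales instead, appropriate when
a study deliberately measures a subset and wants comparability within it.

$S_i$ is graded equidistantly — I (0.8, 1], II (0.6, 0.8], III (0.4, 0.6],
IV (0.2, 0.4], V [0, 0.2], grade I best, $S_i = 0$ assigned to V — and the
verdict compares grades, not raw scores: the step is
$index(\text{before}) - index(\text{after})$ with I = 1 … V = 5, mapped to
excellent (> 1), good (= 1), qualified (0), poor (−1), very poor (< −1).
The published verdict table nominally subtracts scores, but its row
meanings ("increased by one grade") and the worked example (V → IV good,
V → III excellent) only cohere as a grade-index difference, which is what
is implemented. Group-I compliance failures are reported alongside the
verdict and never folded into it; whether a compliance failure should veto
a "qualified" verdict is a policy question the package surfaces as a flag
rather than deciding.

Composite scores are computed at full precision; the published
per-indicator scores were rounded to two decimals before summation, which
propagates up to ~0.003 into the composite (recomputation gives 0.374/0.474
against the published 0.371/0.471). Regression tests on the worked example
therefore check per-indicator scores at display precision (half-away-from-
zero rounding, `round_half_up()`, matching how the published tables round
0.945 to 0.95) and composites within ±0.005.

## The packaged pot experiment and synthetic generators

`pot_experiment()` returns the packaged measurement table: a ryegrass
pot experiment on soil spiked with 5 mg/kg Cd — untreated control, 1% reed
biochar, 1% hydroxyapatite, measured after 70 days. The control has 10
measured indicators (amendment metal and stability are undefined without an
amendment); each treatment has 12; THM, production, edible-part metal and
cost were not measured and illustrate the missing-indicator path.

Two deterministic generators make every code path testable without data
downloads; both are pure functions of their arguments and a seed, and
restore the caller's RNG state.

* `make_consistent_matrix(w, noise, saaty_round)` builds the judgment
  matrix an expert holding true weights `w` would state:
  $b_{ij} = (w_i/w_j)\,e^{\varepsilon_{ij}}$ with Gaussian log-ratio noise
  on the upper triangle, optionally snapped to the nearest Saaty value in
  log space (ratios live on a multiplicative scale), and the lower triangle
  set to exact reciprocals afterwards — the minimal noise model that keeps
  entries positive and reciprocity exact. `make_panel()` draws independent
  experts around a shared truth; with 20 Saaty-rounded experts at noise
  0.05 the aggregated weights recover the truth within 0.05 per component,
  emulating the questionnaire panel the packaged weights came from.
* `make_study(truth, noise)` applies multiplicative log-normal noise to the
  measured values of a truth table (replicate scatter), leaving paired
  before-values and soil totals at their design settings so every generated
  row satisfies the measurement invariants; at noise 0 it returns the truth
  table, so the packaged fixture round-trips byte-for-byte through the
  writer.

What the generators *do not* emulate: correlated errors across indicators,
the temporal dynamics of available metal after amendment (which first
falls, rebounds, and re-falls toward equilibrium — a sampling-time
sensitivity the composite inherits and this package does not model),
multiple simultaneous metals, or expert panels with systematic (rather than
random) disagreement. Passing tests therefore demonstrate the arithmetic
and its conventions, not robustness of the index to those real-data
features.

Problem sizes in the test suite were chosen to exercise the mathematics at
negligible cost: 1000 random matrices of order ≤ 7 for the eigen-oracle
comparison, 20-expert panels, grids of a few thousand points for curve
properties; the full suite runs in a few seconds.

## Worked example

```{r example}
ev <- evaluate_stabilization(pot_experiment(), before = "control")
ev
subset(ev$scores, treatment == "HAP",
       select = c(indicator, value, transformed, score))
```

## Known limitations

* The packaged weights are questionnaire output, shipped as data — the
  package can recompute weights from any panel of judgment matrices, but
  the original 20 questionnaires were not published, so those specific
  numbers are fixtures, not reproducible computations.
* Scoring multiple metals per indicator is an extension beyond the packaged
  single-metal (Cd) design; the registry keys thresholds by metal, but
  combining per-metal scores (minimum vs mean) is left to the caller.
* Weight objectivity: AHP weights inherit the experts' subjectivity;
  dispersion-based corrections (entropy weighting, CRITIC) are out of
  scope.
* No modelling of heavy-metal speciation, microbial or enzyme indicators,
  or life-cycle economics beyond the cost ratio.
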
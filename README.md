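# stabeval

Comprehensive evaluation of the stabilization (immobilization) effect of
amendments applied to heavy-metal-contaminated farmland soil.

Stabilization remediation adds amendments (biochar, hydroxyapatite, lime,
zeolite, ...) to contaminated farmland to reduce the *bioavailable* fraction
of heavy metals without removing the total metal load. Judging whether such
a treatment worked cannot rest on a single number: soil fertility, crop
safety and growth, and the amendment itself all change. `stabeval`
implements a multi-criteria evaluation of that remediation effect for
agronomists and remediation engineers: 16 indicators across soil, crop and
amendment, weighted by an analytic hierarchy process (AHP), normalized by
standardized response curves, and aggregated into a graded before/after
verdict.

## The model

**Weights.** Pairwise-comparison (judgment) matrices on the Saaty 1–9 scale
are turned into priority vectors by the sum-product method: column-normalize
`b_ij / Σ_i b_ij`, sum rows, renormalize. Consistency is checked with
`λ_max = (1/n) Σ_i (Aw)_i / w_i`, `CI = (λ_max − n)/(n − 1)` and
`CR = CI/RI` (tabulated random index); matrices with `CR ≥ 0.1` are
rejected. Expert panels are aggregated as the mean of per-expert priority
vectors after CR filtering, and local weights compose multiplicatively down
the target → criterion → sub-criterion → indicator hierarchy into
comprehensive weights `ω_i`.

**Scores.** Each indicator value (raw, or transformed to a bio-accumulation
factor `BAF = 100·[X]_crop/[X]_soil`, a reduction rate
`α = 100·(X_b − X_a)/X_b`, or a ratio to a local reference) is mapped to
`[0, 1]` by one of three piecewise-linear curves: an S-type rising ramp
between thresholds `L` and `H`, an inverse-S falling ramp, or a
parabolic/midpoint trapezoid `(L1, L, H, H1)` (used for pH).

**Verdict.** The composite score `S_i = Σ ω_i X_i` is graded equidistantly
(I (0.8,1] ... V [0,0.2], I best) and the verdict is the grade step from the
untreated to the treated state: +2 or more excellent, +1 good, 0 qualified,
−1 poor, below −1 very poor. Indicators governed by national standards
(total soil metal, edible-part metal, amendment metal) carry a separate
compliance flag that never silently alters the score.

## Worked example

The package ships the measurement table of a ryegrass pot experiment on
soil spiked with 5 mg/kg Cd: an untreated control and two amendments, 1%
reed biochar (RBC) and 1% hydroxyapatite (HAP), measured after 70 days.

```r
library(stabeval)
ev <- evaluate_stabilization(pot_experiment(), before = "control")
ev
#> Stabilization-effect evaluation
#>   control    Si = 0.164  grade V
#>   RBC        Si = 0.374  grade IV
#>   HAP        Si = 0.474  grade III
#>   RBC vs control: good (grade V -> IV)
#>   HAP vs control: excellent (grade V -> III)
```

The untreated spiked soil scores 0.164 (grade V, the lowest band): the
available Cd is unreduced and the crop accumulates it freely. Biochar lifts
the composite score one grade (verdict *good*), mainly through a 24.9%
reduction of available Cd; hydroxyapatite lifts it two grades (verdict
*excellent*) with a 47.4% reduction and a strong available-P and -K
contribution. Per-indicator detail is in `ev$scores`; AHP building blocks
are exposed directly:

```r
m <- judgment_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1)),
                     labels = c("soil", "crop", "amendment"))
priority_vector(m)
#>      soil      crop amendment
#> 0.6479469 0.2298712 0.1221820
consistency(m)$cr
#> [1] 0.003186783
```

A command-line wrapper is installed at `inst/cli/stabeval`
(`stabeval evaluate --measurements file.csv --before control --report out.json`).

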
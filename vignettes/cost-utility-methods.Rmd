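---
title: "Methods: trial-based cost-utility analysis of two needling interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis of two needling interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlecea)
```

## The analysis

`needlecea` implements a two-arm, trial-based cost-utility analysis
comparing percutaneous needle electrolysis (PNE) with dry needling (DN)
for plantar heel pain, from a hospital perspective over 52 weeks. Both
arms receive four weekly needling sessions; PNE differs only in that the
needle carries a galvanic current from a dedicated device, so the economic
question reduces to whether the equipment cost is justified by the
quality-of-life difference. The chain is:

utilities → LOCF imputation → per-patient QALYs → per-arm costs →
incremental analysis → bootstrap → CEAC and per-week probabilities →
overhead sensitivity.

Each stage is an exported function; `run_full_analysis()` ties them
together deterministically for a given seed.

## Utilities and QALYs

EQ-5D-5L describes health by five dimensions (mobility, self-care, usual
activities, pain/discomfort, anxiety/depression) at five severity levels; a
state is a code such as `"21132"`. A *value set* maps each of the
$5^5 = 3125$ states to a utility index with full health (`"11111"`)
anchored at 1 and a tariff-specific floor (negative values are states
rated worse than dead). `value_set()` accepts a full lookup or additive
disutility coefficients and always validates: anchor at 1, all values in
$[\text{floor}, 1]$, and weak monotonicity (worsening one dimension never
raises the index). Monotonicity violations in a supplied file *warn* rather
than fail — published tariffs are consumed as-is, never re-fitted. The
bundled example tariff is synthetic (constructed for tests; floor
$-0.600$): no national value set is redistributed with the package.

Missing follow-ups are imputed by **last observation carried forward**,
the intention-to-treat convention of the motivating trial. LOCF is
undefined without an origin, so patients with a missing baseline are
excluded, loudly: a warning lists their ids and `run_full_analysis()`
echoes counts in/out into its metadata. Imputed values keep
`observed = FALSE`, so imputation is auditable and idempotent. Utilities
are never truncated or winsorized by the pipeline itself; anything in
$[\text{floor}, 1]$ is legal.

Per-patient QALYs are the trapezoidal area under the utility trajectory
over weeks $0, 4, 8, 12, 26, 52$:

$$\text{QALY} = \frac{1}{52}\sum_k \frac{(u_k + u_{k+1})(w_{k+1}-w_k)}{2},$$

with the deliberate convention **52 weeks ≡ 1 year**, so the 52-week
horizon yields QALYs directly and a constant utility of 1 accrues exactly
one QALY. Two summaries are reported per patient: the integral itself
(`total_qaly`) and the *baseline-anchored gain* (the integral minus
baseline utility held constant). Both are standard in applied work and
they answer different questions; incremental analysis uses `total_qaly`
differences. The trapezoid is cross-checked in the test suite against an
independent dense piecewise-linear integration oracle to $10^{-9}$.

## Costs

The direct-cost model (euros, per session): sanitary consumables,
physiotherapist €43.65, a physiatrist visit €96.03 charged in the first
week only, and for PNE the equipment. Two design choices reproduce the
published course totals exactly and are exposed as switches rather than
buried:

* **Physiatrist exclusion.** The published four-session totals are only
  consistent with the physiatrist visit appearing in the first-week figure
  but not the course total; `include_physiatrist_in_course = FALSE` is the
  default, flip it to change the convention.
* **Sub-cent consumables.** Four sessions at the printed €1.06 miss the
  printed €178.86 total by €0.02; the default stores consumables at
  €1.065, which reproduces it. The printed unit price can be supplied
  instead.

Equipment cost per session comes from an amortization scenario: spread the
€2300 purchase price over the study's own 204 sessions (€11.27), or over a
clinic's expected use (default 816 uses/year — an assumption, back-solved
from a €0.94/session figure at 3-year amortization — and overridable).
The published analysis carries a per-course equipment increment of €22.04
that matches neither scenario (the scenario band is €182.62–€227.70 around
a midpoint of €205.16, while the published PNE total is €200.90); the
package therefore exposes **both paths**: `pne_path = "printed_increment"`
(default; the published increment is an input, giving the €200.90 total)
and `pne_path = "scenario"` with `scenario_band()` summarising the spread
as midpoint ± half-range. Similarly the published €12.21/session for 204
sessions differs from 2300/204 = €11.27; the formula value is computed,
the discrepancy documented.

Overheads are a single fractional uplift on direct costs,
$c \mapsto c(1+f)$ with $f = 0.30$ by default (an upper-bound estimate of
indirect facility costs). Only the single-uplift form is defined — uplifts
do not compose additively.

All currency arithmetic runs on **integer milli-euros** so sums of
sub-cent unit prices stay exact; rounding to cents (half-to-even) happens
only at the reporting boundary (`round_currency()`). Published-table
analogues are rounded at write time: costs to 2 decimals, utilities and
QALYs to 3.

## Incremental analysis and uncertainty

Deltas are PNE − DN throughout. The ICER is $\Delta C / \Delta E$, defined
only when $\Delta E \neq 0$ (a zero QALY difference is flagged, never
divided by). Quadrants on the cost-effectiveness plane follow the signs:
NE costlier/more effective, SE dominant, NW dominated, SW cheaper/less
effective; boundary zeros are assigned to the "not more effective" /
"not costlier" side so that quadrant counts are exhaustive and conserved.

The probabilistic analysis is a nonparametric bootstrap of cost–QALY
pairs: each of the 1000 replicates resamples patients with replacement
*independently within each arm, arm sizes fixed* — the standard scheme for
a two-arm trial, preserving the randomization structure (the within-arm
scheme was an open choice; the alternative, resampling the pooled cohort,
would let arm sizes drift). The CEAC reports, per willingness-to-pay
threshold $\lambda$, the fraction of replicates with strictly positive
incremental net benefit $\lambda\,\Delta E - \Delta C$; ties count as *not*
cost-effective (a convention that matters only on measure-zero events for
continuous costs, chosen strict and documented rather than inferred). The
default $\lambda$ grid is €0–25,000/QALY in €50 steps, €25,000 being the
customary decision threshold. Limiting values are exact: at $\lambda = 0$
the CEAC equals the fraction of cost-saving replicates, and for $\lambda$
beyond every replicate's $|\Delta C/\Delta E|$ it equals the fraction of
QALY-gaining replicates (note the bound must cover cost-saving,
QALY-losing replicates too).

Two ICER conventions are reported because they genuinely differ: the
ratio of means (the point estimate) and `mean_icer()`, the average of
per-replicate ratios over the NE/SW quadrants only. Averaged ICERs are
unstable whenever replicates have $\Delta E$ near zero — the function
warns, and the instability is visible in the acceptance output, where the
seed-to-seed spread of the averaged ICER is orders of magnitude larger
than that of the ratio of means. Consumers should prefer net-benefit
summaries.

The per-week series recomputes per-patient QALYs on truncated horizons
$[0, t]$ for each follow-up week $t$ and reruns the bootstrap. **Full
course costs are attributed at every horizon** by default: the treatment
is complete by week 4, so cost accrual is finished at every follow-up
assessment anyway; an `"accrued"` option scales costs by the fraction of
sessions delivered for grids where that matters.

## The synthetic cohort generator

The motivating trial's patient-level records are not publicly deposited,
so the generator emulates their statistical structure from the published
group summaries. Utility of patient $i$ in arm $a$ at week $t$:

$$u_{it} = \mu_{a,t} + b_i + \varepsilon_{it},\qquad
  b_i \sim N(0, \sigma_b^2),\quad
  \varepsilon_{it} \sim N(0, \sigma_{a,t}^2 - \sigma_b^2),$$

truncated to $[\text{floor}, 1]$. Defaults are the study conditions: 51
patients per arm, the published arm-by-week means and SDs, and a 5% per
visit dropout hazard — the trial reports a high dropout rate without
quantifying it, so 5%/visit (≈ 23% of patients with at least one missing
follow-up over five visits) was chosen once as a realistic mid-range
figure and documented as an assumption. Dropout is monotone (nothing is
observed after the first missed visit) and independent of utility;
informative dropout is deliberately out of scope, though the hazard hook
is where such an extension would live.

Design choices, made once:

* **Gaussian additive model, not a copula or beta model** — only means and
  SDs are published, and this is the simplest model matching them. Skewness
  and ceiling clustering of real EQ-5D data are *not* reproduced; passing
  tests show the pipeline recovers what this model encodes, not that real
  trajectories look Gaussian.
* **Within-patient correlation from the shared random effect only**, no
  autoregressive structure — no longitudinal correlation is published. The
  variance split is `re_share` (default 0.5) of the arm's *minimum*
  per-week variance, since a single patient-level effect cannot exceed any
  cell's total variance; the per-cell occasion variance is the residual,
  and an infeasible explicit decomposition is a configuration error.
* **Deterministic costs per arm** (the trial's costs are protocol-driven);
  cost uncertainty enters only through the equipment-scenario band.
* **Truncation bias is reported** (the per-arm mean shift due to clamping),
  and calibration experiments use untruncated, dropout-free draws so that
  the trapezoid on the spec means is the exact estimand — with dropout,
  LOCF itself shifts the estimand, which is a property of the method, not
  a bug in the generator.

`recovery_experiment()` closes the loop: simulate trials, run the full
pipeline on each, and report bias of the incremental-QALY estimate, the
empirical coverage of the bootstrap 2.5–97.5 percentile interval, and the
CEAC probability distribution. The shipped validation uses 200 simulated
trials × 500 replicates for coverage, and 20 seeds × 1000 replicates for
the per-week probability ordering (week 52 above week 8) — sizes chosen to
give Monte-Carlo error comfortably below the effects being checked.

## Numerical and degenerate-input conventions

* One seeded generator per run; every stochastic function takes a `seed`
  and restores the caller's RNG state. Per-week sub-analyses use
  `seed + k` offsets, so clouds are reproducible yet distinct. Seeded runs
  are byte-identical.
* Currency: integer milli-euro arithmetic; half-to-even rounding to cents
  at reporting only.
* $\Delta E = 0$: ICER undefined and flagged; the CEAC is still defined.
* Empty arms, non-grid weeks, missing baselines, zero amortization
  divisors, negative overhead fractions: immediate errors with the
  offending patient/state/parameter named.
* Zero-variance cohorts bootstrap to the point estimate exactly; a
  single-observation cell reports SD 0 (degenerate descriptive tables
  remain printable).

## Known limitations

* LOCF is the trial's convention and is implemented faithfully, but it is
  a strong assumption under the observed dropout; no multiple-imputation
  alternative is provided.
* The generator cannot manufacture information the published summaries do
  not contain: patient-level QALY means under it equal the
  trapezoid-on-means values in expectation, which differ from the
  published per-arm QALY gains (whose derivation from the summaries is not
  reconstructible); both `total_qaly` and `baseline_anchored_gain` are
  reported for transparency.
* No discounting (single-year horizon), no indirect/societal costs, no
  parametric PSA, no comparison against usual care — all deliberately out
  of scope.
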
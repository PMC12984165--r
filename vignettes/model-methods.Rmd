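---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocea)
```

## The decision problem

`mammocea` models a national breast-cancer screening programme that invites
women aged 50–69 to biennial mammography, and asks what happens — clinically
and economically — if the conventional double-reading workflow (two
radiologists, arbitration for discordant reads) is replaced by an AI
companion reader (AI replaces the second radiologist) or by standalone AI
interpretation. The three strategies differ *only* in test characteristics
and per-scan price:

| strategy | sensitivity | specificity | per-scan cost (2023 SGD) |
|---|---|---|---|
| conventional double reading | 0.691 | 0.954 | 110 |
| AI companion reader | 0.715 | 0.968 | 97.50 |
| standalone AI | 0.805 | 0.893 | 80 |

The per-scan prices follow a fee-substitution rule: the SGD 110 double-read
price includes two radiologist interpretation fees; the companion strategy
replaces one fee with the SGD 5 AI service fee, the standalone strategy
replaces both. Only the three endpoint prices are published; the single
consistent read fee linking them is SGD 17.50 (from 110 − 2r + 5 = 80), and
`derive_scan_costs()` keeps the rule checkable in both directions.

## The Markov cohort model

A closed cohort of 10,000 women enters at age 50 and is followed in annual
cycles over a 50-year horizon. The state space has 23 states: `Healthy`;
undiagnosed preclinical cancer `Undx(s)` for stages 0–IV; `Diagnosed(s)`
(one cycle of curative-intent treatment); `Remission(s)` (lifelong annual
surveillance); `Recurrence(s)` (one cycle of recurrence treatment, then
back to remission); and two absorbing dead states (breast cancer / other
causes). Recurrence is economically a single condition — its cost and
utility are stage-invariant — but it is carried per stage internally purely
so that a woman returns to the remission state matching her stage at
diagnosis; reporting aggregates the five sub-states.

Screening is applied in cycles where the age is in the invitation window
and `(age − 50) mod 2 = 0` — ten rounds at ages 50, 52, …, 68. Annual
cycles were chosen rather than biennial ones because surveillance,
recurrence and mortality are annual processes; screening is simply switched
on in alternating cycles.

### Event composition within a cycle

Within one cycle, events compose as conditional competing risks in a fixed
order: (1) other-cause death by age; (2) breast-cancer death by stage;
(3) screen detection (screening cycles only, probability
compliance × sensitivity for a living woman with preclinical disease);
(4) clinical/interval presentation by stage; (5) preclinical stage
progression; (6) onset (Healthy → Undx(0)); (7) the deterministic
treatment → remission, remission → recurrence and recurrence → remission
moves keyed on the start-of-cycle state. Each later event is conditioned on
the earlier ones not occurring, so every transition row is a valid
probability vector *by construction* — no rate-to-probability conversion is
needed and row sums are asserted to 1 within 1e−12. Interval cancers are
not a separate state: they are `Undx → Diagnosed` transitions via clinical
presentation in non-screening cycles or after a false-negative screen, and
the event ledger tallies them separately from screen detections.

Breast-cancer mortality applies while undiagnosed and during the treatment
cycle (by stage) and during recurrence (its own rate); women in remission
can die of breast cancer only after recurring. One modelling consequence is
that undiagnosed disease kills without ever being counted as a diagnosis,
which is the intended reading of registry-style mortality.

### Burn-in prevalence

The cohort enters disease-free at age 49 and runs one pre-screening cycle
(onset, progression, clinical presentation, mortality — no screening).
The resulting occupancy is the model's t = 0, so the first invitation at
age 50 already faces a realistic preclinical prevalence.

### Compliance

The 40% national attendance rate (20% and 80% as scenarios) is modelled as
an independent per-round attendance probability applied to the expected
cohort — the simplest reading of programme-level compliance. A
`fixed`-attender variant (a lifelong 40% subgroup attends every round) is
exposed via `screening_policy(attendance_model = "fixed")` for sensitivity
exploration; it runs the engine at compliance 1 and 0 and mixes the traces.

### Half-cycle correction

Off by default: costs and QALYs are booked at cycle start with the same
discount exponent, which treats the two streams symmetrically and avoids
artefactual ICER shifts. `screening_policy(half_cycle = TRUE)` switches to
averaging adjacent occupancies.

## Economics

Per cycle the model books: screening cost (attendances × per-scan price);
recall work-up (every true or false positive is recalled to ultrasound,
half of recalls — a configurable fraction, the published sources price the
procedures but not the split — proceed to biopsy); stage-specific treatment
cost for the occupancy under treatment; remission surveillance at 5% of the
stage treatment cost per year; and the stage-invariant recurrence cost.
QALYs are occupancy × utility. Both streams are discounted at 3% per year.
True-positive work-up is priced identically to false-positive work-up: the
recall cascade does not distinguish them until pathology.

`incremental()` reports ΔC, ΔE, the ICER and net monetary benefit
(NMB = WTP × ΔE − ΔC) at the SGD 50,000/QALY threshold. A cheaper,
more effective candidate yields a negative ICER which is reported as
"dominant (cost-saving per QALY gained)" alongside the signed ratio; a zero
QALY difference suppresses the ratio entirely. ICERs are always computed
from full-precision totals — dividing rounded table cells gives visibly
different ratios (e.g. −19,880 rather than −19,846 per QALY on the
published totals), so rounding happens only at report time.

## Uncertainty analysis

**One-way deterministic (tornado).** Each listed parameter is set to 0.9×
and 1.1× its base value (all others at base), the *full* pipeline is re-run
for both strategies in the comparison, and parameters are sorted by the
width of the resulting ICER range. Probabilities that leave [0, 1] are
clipped with an audible warning. The default parameter list covers the
strategy sensitivities and specificities, the three per-scan costs,
compliance, biopsy cost, stage-I treatment cost and the recurrence and
stage-I utilities. The tornado also reports whether the base-case ICER lies
inside each parameter's envelope: ICERs are ratios and need not respond
monotonically, and such rows are flagged rather than hidden.

**Probabilistic (PSA + CEAC).** Costs are drawn from Gamma distributions
with mean at the base value and a 5% coefficient of variation (an absolute
SGD SD is meaningless across costs spanning two orders of magnitude);
utilities from Beta distributions with mean at the base value and absolute
SD 0.05. Both dispersions are config-exposed. Shapes come from method of
moments: Beta ν = m(1−m)/s² − 1, α = mν, β = (1−m)ν; Gamma shape = (m/s)²,
scale = s²/m. Test characteristics, compliance and the discount rate are
structural and never sampled. Each draw perturbs one parameter set shared
by all three strategies (common random numbers), and — because prices and
utilities do not enter the transition dynamics — each strategy's cohort
trace is computed once and re-priced per draw through the same
`accumulate()` code path used for the base case. At each point of the WTP
grid (default 0–100,000 SGD in 2,500 steps, covering the decision-relevant
landmarks at 30,000–50,000) the strategy with the highest NMB is counted,
ties resolved to the first strategy in conventional → companion →
standalone order (ties have measure zero under continuous sampling).
Reproducibility comes from one root seed that spawns per-draw child seeds.
Draws producing non-finite results are rejected and logged; more than 1%
rejections aborts the run.

Because the healthy-state utility is a population norm of 0.92 rather than
1.0, the Beta moment condition s² < m(1−m) holds for every sampled utility;
a utility of exactly 1 would make mean-preserving Beta sampling degenerate,
and `sample_psa_draw()` raises a named error in that case.

## The synthetic natural history

The registry and hospital tables behind the original Singapore evaluation
are not redistributable, so `generate_bundle()` synthesises a complete,
internally consistent stand-in (every file derived from it is labelled
synthetic). Defaults, chosen once as field-plausible values:

* **Onset**: logistic in age, asymptote 0.003/yr, midpoint 60, width 8 —
  lifetime preclinical onset risk ≈ 9.7%, i.e. about 1 woman in 10.
* **Preclinical dwell**: mean 2 / 2 / 1.5 / 1.25 years in stages 0–III
  (progression probability the reciprocal), giving a mean preclinical
  sojourn of a few years, the window screening exploits.
* **Clinical presentation**: 0.05 → 0.80 per year from stage 0 to IV;
  late-stage disease rarely stays undetected long.
* **Breast-cancer mortality**: 0.001 → 0.30 per year by stage; 0.25 in
  recurrence. **Other-cause mortality**: Gompertz-like, 0.002 at age 50
  growing 8.5%/yr, with small seeded lognormal jitter (then restored to
  monotone) to emulate registry granularity.
* **Economics**: stage treatment costs SGD 20,000 × 1.5^stage (20k–101k),
  remission surveillance 5% of stage cost/yr, recurrence SGD 40,000/yr,
  ultrasound SGD 180, biopsy SGD 800, half of recalls biopsied.
* **Utilities**: healthy 0.92, preclinical 0.90, diagnosed 0.86–0.48 by
  stage, remission 0.84, recurrence 0.60.

The generator emulates the *structure* of real inputs — rising incidence,
ordered stage costs and utilities, registry-like mortality — not their
values. Consequently the model's absolute counts and totals are
internally valid but are not estimates for Singapore; what passing tests
demonstrate is the correctness of the machinery (conservation, composition
order, economics, uncertainty propagation), plus the qualitative orderings
that follow from the published test characteristics alone (FP:
companion < conventional < standalone; FN: standalone < companion <
conventional; specificity dominating the tornado).

## Validation by microsimulation

`microsimulate()` is a deliberately independent implementation: individual
women, explicit Bernoulli events in the same composition order, no shared
code with the matrix engine. At n = 200,000 histories every cohort-engine
tally agrees with the microsimulation within 3 standard errors (the test
suite checks all three strategies at 40% compliance at full n, and the
20%/80% scenarios at smaller n). This is the package's central correctness
property: two structurally different computations of the same expectation
agreeing at Monte-Carlo precision.

## Problem sizes and numerical choices

The test suite runs the full 50-cycle cohort engine everywhere it is
cheap (~20 ms per run), the 200,000-woman microsimulation once per
strategy, 10,000 method-of-moments recovery draws, and CEACs at 150–200
draws per scenario; the acceptance script uses 2,000 PSA draws per
compliance scenario. Occupancy conservation is enforced at 1e−6 persons
per cycle (hard failure), transition rows at 1e−12. All money stays in
full-precision SGD floats; tables round money to 2 d.p. and QALYs to
1 d.p., with a full-precision JSON companion written alongside.

## Known limitations

* The synthetic natural history reproduces structure, not Singapore's
  registry values; absolute outputs are demonstrational.
* No psychological disutility of false positives or overdiagnosis is
  modelled; false positives carry only work-up costs.
* Sensitivity and specificity are fixed scalars — no reader variability,
  threshold drift or age dependence.
* The cohort is homogeneous: no ethnicity, comorbidity or risk-group
  heterogeneity, and no operational constraints (workflow integration,
  regulatory approval).
* Stage granularity for reporting splits early = {0, I, II} versus
  late = {III, IV}.
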
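---
title: "Methods: the her2cea Markov cohort cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the her2cea Markov cohort cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2cea)
```

## The decision problem and the model

`her2cea` evaluates one year of adjuvant trastuzumab after chemotherapy
versus chemotherapy alone in HER2-positive early breast cancer, from the
Dutch health-care perspective in 2012 euros. The engine is a
deterministic Markov cohort model with four health states — disease free
(DFS), locoregional/contralateral/new-primary recurrence (LR), distant
metastases (DM) and dead — annual cycles, and a lifetime horizon. Flow
is forward-only: DFS → {LR, DM, dead}, LR → {DM, dead}, DM → dead.
Cardiac toxicity is not a state: it occurs in the first year only and
attaches a one-cycle disutility (and a monitoring cost) to the affected
fraction, leaving state membership untouched.

### Survival inputs and treatment effect

All transition inputs are annual probabilities derived from exponential
survival functions, split into a first-year and a subsequent-year value.
Under the exponential assumption probability and hazard rate
interconvert exactly (`rate_from_prob()`, `prob_from_rate()`), and a
hazard ratio $h$ maps an annual probability as
$p' = 1-(1-p)^{h}$ (`apply_hazard_ratio()`).

The direction convention matters: the baseline survival schedules are
the *trastuzumab-arm* observations, and the trial hazard ratios
(trastuzumab vs control, $h<1$) are inverted to derive the control arm —
its hazard is the trastuzumab hazard divided by $h$. The treatment
effect lasts `benefit_duration` cycles (8 in the base case, 4 in the
sensitivity setting); afterwards the hazard ratios are assumed to be 1,
which we implement by letting the control arm revert to the shared
baseline schedule. Scenarios with directly observed control-arm survival
(the trial configuration) supply explicit `control_transitions`, used
during the benefit period and likewise reverting afterwards — this
reconciles "both arms observed in the trial" with "no effect after the
benefit period" in one mechanism.

The annual LR probability is not observed directly but derived as
$\max(0,\; p_{\mathrm{DFS\,event}} - p_{\mathrm{DM}})$: the composite
DFS-event endpoint counts any recurrence, DM counts distant events, and
their difference is the local component. Trial-style inputs can have
$p_{\mathrm{DFS}} < p_{\mathrm{DM}}$, in which case the LR state is
simply unused and carries no costs.

### Mortality

DFS and LR occupants die of other causes at the age-specific rate of an
all-cause female life table (attained age = start age + cycle − 1;
ages past the table end are clamped to the last row so the horizon is
finite). DM mortality is not a printed input; by default the package
*derives* it each cycle so that the cohort's total death flow tracks the
overall-survival input: excess deaths
$= \max(0,\; p_{\mathrm{OS}}\times\text{alive} - \text{background
deaths})$, attributed to DM occupants and capped at probability 1. The
rationale is that the model parameterises $1-\mathrm{OS}$ directly and
cancer death is routed through the DM state. Two consequences are worth
knowing: in the first cycles DM occupancy can be too small to absorb the
implied cancer deaths (the cap binds and total mortality temporarily
undershoots the OS input), and at old ages background mortality may
exceed the OS input (the floor at zero binds, mortality overshoots). A
fixed annual DM death probability can be configured instead
(`dm_mortality = <value>`), which also makes the chain time-homogeneous
for analytic cross-checks.

### Competing risks

Within a cycle, exit probabilities from a state are converted to rates,
summed, and the total exit probability $1-e^{-\sum r_i}$ is allocated to
causes proportionally to their rates. This is exact for constant hazards
and guarantees exits never exceed occupancy (naive subtraction of
probabilities can exceed 1). If several causes have probability exactly
1, the certain exit is split equally among them — an arbitrary but
documented tie-break that only degenerate inputs can reach.

### First-year accounting, half-cycle correction, discounting

Costs and utilities differ between the first year *in a state* and
subsequent years. "First year" is tied to time since entering the state,
not calendar time, implemented by tunnel compartments: entrants spend
exactly one cycle in `lr1`/`dm1` before moving to `lr2`/`dm2`. For DFS
the entry year is cycle 1, since the whole cohort starts there.
Occupancy is half-cycle corrected (the mean of successive cycle
boundaries), so a surviving entrant accrues half a year at entry-year
rates in the entry cycle and the other half in the next cycle — one full
entry year in total. Costs are discounted at 4.0%/year and effects at
1.5%/year with cycle 1 undiscounted; the timing convention is not
externally fixed, so it is explicit in `discount_factor()`.

### Cardiac toxicity

The first-year cardiac event fraction multiplies the 0.128 disutility
(0.728 DFS utility minus 0.600 symptomatic-heart-failure utility) for
one discounted cycle, in both arms (the control fraction is the
trastuzumab fraction divided by the relative risk). The €467 monitoring
cost is interpreted as *monitoring*, applied to the whole trastuzumab
arm in year 1 and to neither control patients nor event fractions; the
alternative reading (cost attaches to the event fraction) is available
via `cardiac_monitoring_scope = "events"`.

## Parameters and defaults

Printed, public inputs (used verbatim in the bundled real-world
configuration): the six survival rows (e.g. subsequent-year
$1-\mathrm{OS}$ = 0.026, SE 0.006, Beta), the six state-cost rows (e.g.
DM first year €30,165, SE €2,339.46, Gamma), cardiac monitoring €467,
3 vials of 150 mg per cycle, 15 administrations, €605/vial and €257 per
day-care administration (both tariff-fixed), DFS first-year utility
0.728, the 0.128 cardiac disutility, discount rates 4.0%/1.5%, the
€80,000/QALY threshold, and the effective population 1,743/year for 10
years at 4%.

Inputs that are *not* public ship as synthetic placeholders, flagged in
each config's `synthetic_fields` and chosen once, as follows:

* **Trial hazard ratios** `hr_dfs = hr_os = 0.76`, `hr_dm = 0.75`:
  plausible magnitudes for a 1-year trastuzumab effect at long
  follow-up; they are required config inputs with no hidden defaults.
* **Cardiac inputs** `p_cardiac = 0.125`, `rr_cardiac = 5.33`: chosen so
  the deterministic cardiac QALY decrements, $0.128 \times 0.125 =
  0.016$ and $0.016/5.33 \approx 0.003$, reproduce the reported
  magnitudes; 10–15% first-year cardiotoxicity under trastuzumab with a
  roughly five-fold relative risk is clinically realistic.
* **Utilities beyond DFS year 1** (the published utility table is
  truncated): DFS subsequent 0.80, LR 0.71, DM 0.60, anchored to the
  reported QALY/LY ratios per state (≈0.80, 0.71, 0.60).
* **Start age 55**: a plausible cohort mean where only background
  mortality depends on it.
* **`hr_dm_after_lr = 1`**: the extra DM risk after local recurrence has
  no printed value; the default assumes none, and the loader logs when
  the field is absent. Raising it shortens LR sojourn and increases DM
  flow.
* **Life table**: `synthetic_life_table()` is Gompertz-shaped (0.0025 at
  55, doubling every 8 years, capped at 0.6); real analyses should use
  the official national table via `read_life_table()`.
* **Guideline and trial survival tables**: subgroup and trial estimates
  are not public; the bundled values are labelled perturbations at the
  same scale.

Because of these placeholders the bundled base cases are
*methodologically* faithful but not clinically quotable; with them the
trial scenario yields a positive ICER, whereas trial-based evaluations
of this comparison typically find trastuzumab dominant — an outcome that
hinges on trial-arm DM costs and survival that are not publicly
available here.

## Probabilistic sensitivity analysis

Every Beta/Gamma row of the input tables varies in PSA; tariff prices,
utilities (no published SEs) and the hazard ratios (assigned no
distribution) stay fixed. Shapes come from the method of moments; a
reported SE of 0 or `NA` makes a parameter fixed, and a Beta SE at or
above $\sqrt{m(1-m)}$ is truncated to 0.999 of that bound with a
warning. Draws are quantile-based — a uniform deviate mapped through
`qbeta()`/`qgamma()` in a canonical, documented parameter order — which
gives two properties for free: sequence-level reproducibility across
platforms, and common-random-numbers coupling, so scaling all SEs toward
zero (`se_scale`) contracts every draw monotonically to its mean and the
EVPI-shrinkage property is exact rather than asymptotic, under a shared
seed. Both arms are built from one draw, so shared parameters are
perfectly correlated and the control arm inherits the trastuzumab draw
through the hazard-ratio division.

One documented limitation: with the full published SEs (some Beta rows
have SE > mean, e.g. 0.054 ± 0.067) the model response is visibly
nonlinear, so the PSA mean of ΔQALY differs from the deterministic
plug-in value by more than Monte Carlo error (Jensen bias, about 2% of
ΔQALY here). The test suite therefore checks plug-in consistency in the
near-linear regime (`se_scale = 0.25`) and treats the full-SE bias as a
property of the model, not a bug.

The CEAC reports, per willingness-to-pay λ, the fraction of iterations
with positive incremental net monetary benefit λ·ΔE − ΔC. Per-patient
EVPI is E[max(NMB)] − max(E[NMB]); population EVPI multiplies it by
$\sum_{t=1}^{10} 1743/1.04^{\,t-1}$ ≈ 14,703 (first annual cohort
undiscounted; the alternative convention differs by one factor of 1.04
and is available via `first_year_discounted = TRUE`).

## The synthetic cohort generator

`generate_cohort()` emulates the *design* of the source cohort study so
the estimation path is testable end to end: piecewise-exponential event
times (one rate before, one after t = 1) for three latent processes (LR,
DM, death), with the cause-specific LR rate set to the composite
DFS-event rate minus the DM rate so that min(LR, DM) has exactly the
composite rate; uniform administrative censoring on [3.8, 6.8] years
(staggered accrual with a fixed cut-off); death times censoring the
recurrence endpoints; Bernoulli first-year cardiac events; and skewed
Gamma per-patient annual costs whose population SE-of-mean matches the
cost table at the source cohort's size (n ≈ 230). `estimate_inputs()`
is the matching maximum-likelihood estimator — events over person-time,
follow-up split at t = 1 — and `estimates_to_config()` writes the
estimates back into a scenario configuration.

What the generator deliberately does **not** emulate: confounding by
indication (the analysis takes relative effects from the trial
precisely to avoid it), treatment crossover, non-exponential hazards,
and any correlation between costs and event times. A green
parameter-recovery test therefore establishes that the estimator and
model are consistent with each other under the stated data-generating
assumptions — not that those assumptions hold in any real registry.

## Numerical choices

* Probability conservation is enforced to 1e−12 per cycle; occupancy
  sums are validated on entry to `transition_step()` (1e−9 tolerance).
* The cohort runs until the dead fraction reaches 1 − 1e−6 or attained
  age 110, whichever comes first; a numeric `horizon` overrides this.
  A run that ends at the age cap with less than 5% dead warns — that
  only happens under degenerate (near-zero-mortality) inputs.
* ICERs are kept unrounded internally; the south-west quadrant (cheaper,
  less effective) reports the ratio with an explicit `sw_flag` instead
  of a bare number, since a bare SW ratio inverts the decision rule.
  ΔE = 0 yields a label by the sign of ΔC.
* The probability↔rate conversions use `log1p`/`expm1` for accuracy near
  zero; p = 1 is rejected (infinite rate) rather than approximated.
* Seeds: `run_psa()` seeds the session RNG and restores the caller's
  state on exit; the generator takes its own seed argument.

## Known limitations

* Placeholder inputs (hazard ratios, cardiac probability, non-DFS
  utilities, guideline/trial tables) make the shipped numbers
  scale-correct but not decision-grade; every placeholder is a config
  field a user with access to the real sources can overwrite.
* The derived DM-mortality rule's cap/floor behaviour (above) slightly
  distorts the death-timing at the extremes of the age range.
* One-year cycles with half-cycle correction approximate mid-cycle
  event timing; no continuous-time or shorter-cycle variant is offered.
* EVPPI/EVSI (partial and sample information values) are out of scope.
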
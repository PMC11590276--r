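---
title: "Methods: bottom-up matched-control costing of CKD"
author: "ckdcost"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the methodological and numerical choices behind
`ckdcost`: the rules the pipeline implements, the places where a design was
genuinely open and what was decided, what the synthetic generator does and
does not emulate, and the limits of what a passing test suite shows.

# The estimand

The quantity of interest is the direct healthcare cost *attributable* to
chronic kidney disease: for each CKD case, the difference between their
costs and the costs of a matched person without CKD over the same length of
follow-up, per component (emergency, non-dialysis hospital, medication,
primary care, community pathology, dialysis, outpatient renal services),
expressed per person-year within each KDIGO stage. This is a
government-perspective, bottom-up design: individual utilisation is priced
and summed, rather than apportioning aggregate expenditure top-down. The
single exception is outpatient renal-clinic (and, in real applications,
home-dialysis) expenditure, which is not observable per person and is
allocated top-down across stages by frequency weights
(`allocate_topdown()`, largest-remainder reconciliation so stage shares
re-sum to the total to the cent).

# Staging rules and their edge cases

**eGFR.** `compute_egfr()` implements the 2009 CKD-EPI creatinine equation
*without* the race coefficient, matching Australian laboratory reporting
practice; creatinine in µmol/L is converted to mg/dL by division by 88.4.
The choice of the 2009 equation (over the 2021 refit) follows what
Australian laboratories reported in the study period; switching equations
would shift stage boundaries slightly but not the pipeline's structure.

**Chronicity.** CKD requires two qualifying results strictly more than 90
calendar days apart — "over 90 days" is read as `> 90`, so day 0 and day 91
qualify and day 0/day 90 does not — with *every* other result of the same
analyte dated inside the window also qualifying. Albuminuria uses
sex-specific uACR cut-offs (≥ 2.5 mg/mmol male, ≥ 3.5 female).

**Onset and confirmation dates.** The chronicity rule does not by itself fix
the date a confirmation takes effect. We use the date of the *second* test of the
earliest qualifying pair: the earliest day on which the chronicity evidence
exists. Stage periods begin then, and the day a new stage is confirmed
belongs to the new stage.

**Pair spanning two stages.** When the two tests of a qualifying pair imply
different stages, the least severe is used. All qualifying pairs generate
confirmation events, so a later same-band pair still confirms the more
severe stage on its own evidence.

**Ratchet.** The stage on any day is the most severe stage confirmed on or
before that day; improved eGFR never lowers it. Confirmations from prior
years carry forward into the analysis year. Any dialysis-coded (Z49)
admission forces Stage 5 from its date. Transplant recipients are not a
separate category (they are staged by eGFR like everyone else), and dialysis
modalities are not distinguished within Stage 5.

**Stages 1–2.** An albuminuria confirmation alone does not determine a
stage; it is staged against the most recent eGFR on or before the
confirmation date (≥ 90 with albuminuria → Stage 1, 60–89 → Stage 2; below
60 the eGFR grid applies). A person with confirmed albuminuria but *no*
eGFR on or before the confirmation cannot be staged; the history is
returned empty with an `unstageable` attribute, and the pipeline excludes
such persons from both cases and controls.

**Follow-up.** A person with no pathology, hospital, emergency or mortality
record in the analysis year and none after it is lost to follow-up and
excluded, even if earlier records identify CKD. Death in the year truncates
the window at the death date.

The staging algorithm is verified against a brute-force oracle that
re-derives, for every calendar day, the most severe stage confirmed by the
records up to that day; the interval construction must agree exactly, for
every person of a generated cohort.

# Matching

Matching is exact on five covariates — 5-year age band, sex, indigenous
status, remoteness, evidence of diabetes (two HbA1c > 6.5% or two fasting
glucose > 7.0 mmol/L, re-derived from labs, not taken from the generator's
flag) — relaxed in the fixed order remoteness → sex → indigenous status.
Decisions the matching design leaves open:

* **Age band and diabetes are never relaxed** — the relaxation ladder names
  only the other three, and both are strong cost confounders.
* **Greedy assignment in a stable order** (cases sorted by id), with the
  control drawn uniformly at random among those available at the
  least-relaxed feasible level, **without replacement**. An optimal
  (flow-based) assignment could match slightly more cases but is opaque;
  greedy is reproducible and auditable, and the test suite audits it
  against exhaustive stricter-level search: no case may sit at a relaxation
  level while an unused stricter-level control was available when it was
  processed.
* **Apportioning is anchored to the analysis year**: a matched control's
  annual ledger is scaled by `case_followup_days / 365` rather than
  calendar-aligned to the case's window — the simplest reading of
  proportional adjustment. A case occupying several stages in the year
  keeps one control, with both ledgers restricted/scaled per stage period.

# Costing conventions

* Every priced unit (admission, presentation, script, collection, billed
  item) is rounded to the cent individually, so ledgers are exactly
  additive over any window split or event partition; rounding to whole
  dollars or millions happens only at report time (half away from zero —
  base R's banker's rounding would turn 99.98 into an even-digit
  neighbour).
* A cost belongs to the stage period containing its event date.
* A pathology "collection" is all items for one person on one date from one
  provider; the coning rule pays the collection and bulk-billing fees plus
  the three most expensive items (ties at third place broken by item code;
  the sum is tie-invariant).
* Medication scripts cost `(1 + n_repeats) ×` the tier-weighted PBS price
  plus dispensing, handling and safety-net recording fees.
* Inflation to 2023 AUD is a per-year multiplier owned by the catalog
  (configuration, not code). Tables priced directly in 2023 dollars (the
  emergency averages here) carry a unit multiplier — both readings of
  "inflate 2019 prices where available, use 2023 prices otherwise" are
  therefore expressible in the catalog alone.
* Unknown codes are collected across all components of a ledger build and
  reported in a single missing-price error.

# Cost models and transfer

Medication, GP and pathology costs are typically observed only on
sub-datasets (a general-practice extract; the subset of persons with > 95%
— strictly — of community pathology from the most complete provider).
`fit_cost_glm()` fits a gamma GLM with log link on the five fixed
predictors (stage with reference `"None"`, sex ref female, youngest age
band, non-indigenous, major cities), via IRLS, with Pearson dispersion.
Models are compared by AIC with BIC alongside; when they disagree AIC wins
(a fixed tie-break, recorded in the comparison table).

Zero costs are incompatible with the gamma likelihood, and no single
handling is canonical, so two policies are implemented:

* `epsilon_shift` (default): zeros become 0.01 AUD. Fitted means then track
  the full-cohort mean including zero-cost years, which is the quantity the
  attribution step needs.
* `positive_only`: fit on positive costs, scale predictions by the observed
  positive fraction per stage — a two-part-model reading, available for
  sensitivity analysis.

Predictions are `exp(linear predictor)`, strictly positive; unseen factor
levels are an error naming the level. In the pipeline, predictions replace
the observed medication / primary-care / pathology components for cases
(at the period's stage) and their controls (at `"None"`), mirroring how
modelled costs are transferred to a full cohort; stages absent from a
model's training data fall back to observed costs with a warning.

The fitter is cross-checked in tests against a direct evaluation of the
gamma log-density at the fitted parameters (relative tolerance 1e-6),
coefficient recovery at n = 20,000 (absolute bias < 0.02 per coefficient),
and 95% Wald coverage over 100 replicates at n = 5,000.

# Attribution and reporting

Component differences keep their sign — negative attributable costs are
evidence, not noise, and truncating them would bias totals upward. Person
years use a 365-day year (the default analysis year, 2019, is not a leap
year). Stage means per person-year are ratio estimates, Σ diffs / Σ
person-years; the stage total is the sum of its component means, and the
grand total equals the person-year-weighted sum of stage totals by
construction. Component shares are integer percentages of the grand total
and must sum to 100 ± 1.

# Extrapolation

National case counts transfer stratum rates: cases divided by the local
population of the demographic cell (sex × indigenous × age band ×
remoteness), times the national population of the cell, summed over
stage-specific strata and multiplied by the per-case attributable cost.
Identity (national = local populations) and linearity (k × populations →
k × totals) are tested exactly. Two decided open points:

* **Rounding order for undiagnosed estimates:** multiply population ×
  albuminuria proportion × >90-day persistence in full precision, round the
  estimated count once, then subtract observed cases. This reproduces the
  published Stage 2 subtraction exactly; the Stage 1 published figure sits
  one unit away from any rounding order because it was derived from
  unprinted intermediates, and the package reports its own computed value.
* **Demographic cells present nationally but absent locally** borrow the
  stage's marginal local rate and mean cost, with a warning. Cells with
  local population but zero cases are genuine zero-rate strata and
  contribute zero — the pipeline writes them explicitly so the fallback
  never fires on them.

# The synthetic generator

`generate_cohort()` emulates the conditions this kind of analysis faces;
its defaults are the package's study conditions and are not tuned per run:

* **Stage prevalence** ~12% diagnosed CKD, split across stages roughly in
  proportion to the person-year distribution reported for the Western
  Australian cohort (3a dominant, early stages thinned by sparse uACR
  testing); 24% of non-early-stage persons ever receive uACR testing.
* **Confounding:** diabetes prevalence by stage is U-shaped (≈ 44–49% in
  Stages 1–2, ≈ 12–20% in Stages 3–5, 8% in controls), and age, indigenous
  status and remoteness distributions differ by stage, so matching and
  relaxation are genuinely exercised.
* **Trajectories are built backward from the true stage:** two confirmatory
  results 91–365 days apart placed before the analysis year, interim and
  in-year monitoring results confined to the same eGFR band, uACR pairs
  above the sex threshold for Stages 1–2, diabetes labs consistent with the
  flag. A configurable fraction of no-CKD persons get "inconsistent
  interim" trajectories (sub-60 pair with a ≥ 60 interim) that staging must
  reject.
* **Costs are gamma-with-zero-mass:** per component and stage, a zero-cost
  year with configured probability, otherwise a gamma person effect times a
  Poisson event count with intensity `mean / expected event cost`, so the
  priced annual cost has the configured mean. The per-event expectation is
  evaluated through the costing functions themselves
  (`expected_event_cost()`), keeping generator and coster consistent to the
  cent. Stage mean profiles equal a no-CKD baseline plus per-stage
  increments following the reported attributable cost-per-person-year
  profile, with the baseline chosen so the overall case-over-control uplift
  is about 75% under the default stage mix.
* **Not emulated:** comorbidity beyond diabetes (real CKD cohorts are
  "sicker" than controls in ways matching cannot absorb, which biases real
  attributable costs upward), provider-specific test menus, within-year
  incident CKD under the default settings (stages are confirmed before the
  year; in-year progression is exercised by tests, not defaults),
  transplant-specific costs, seasonality, and record-linkage error
  (identifiers arrive pre-linked).

Passing tests therefore show the *pipeline* is correct under its stated
assumptions — staging matches the day-by-day rule, accounting is exact,
estimators recover configured truth — not that real-world attributable
costs are unbiased: on real data the residual-confounding caveat above
dominates.

# Problem sizes and tolerances

The shipped checks use sizes chosen to make sampling error small relative
to the quantities checked while keeping runs quick: oracle staging on
200-person cohorts, matching audits on 50-case instances, GLM recovery at
n = 20,000 (bias < 0.02) and coverage over 100 replicates at n = 5,000, and
a 10,000-person end-to-end run whose stage-specific attributable means must
land within 3 standard errors of the configured values. Accounting
identities (ledger additivity, top-down conservation) are exact to the
cent; statistical checks use fixed seeds so results are reproducible.

# Known limitations

* Greedy matching can leave cases unmatched that an optimal assignment
  would match; unmatched cases (disproportionately those with rare
  covariate patterns) drop out of the attributable totals.
* The gamma GLM with epsilon-shifted zeros approximates stratum means well
  at the shipped settings but is not a two-part likelihood; `positive_only`
  exists for sensitivity, and the two are compared by AIC/BIC on identical
  rows only.
* The undiagnosed adjustment inherits single-measurement survey
  proportions and the >90-day persistence estimate as fixed parameters; no
  uncertainty is propagated.
* Stage 5 mixes dialysis and non-dialysis patients; per-person dialysis
  costs are correspondingly diluted averages.
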
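---
title: "Quantifying parent engagement: the PPP and PEI indices"
author: "engage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parent engagement: the PPP and PEI indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engage)
```

## The measurement problem

School- and family-based health interventions for children routinely invite
parents to take part — evening events, take-home activities, online lessons —
and routinely evaluate them with surveys, diet recalls, and accelerometry.
Yet "parent engagement" is usually reduced to attendance or a yes/no
participation flag. Two features of real designs make that reduction
misleading:

1. **Asymmetric opportunity.** In a cluster-randomized design, different
   cohort × school cells (*arms*) offer different activity menus. A parent
   who did 2 of 2 offered activities is maximally engaged; a parent who did
   2 of 8 is not. Raw counts are not comparable across arms.
2. **Heterogeneous burden.** Attending a two-hour evening event with your
   child is a different commitment than clicking through a 15-minute online
   module. Breadth of participation alone cannot see this.

This package implements a scoring schema that addresses both, with two
indices per parent:

* **Parent Participation Profile (PPP)** — breadth: the number of distinct
  activity *types* the parent attempted, where "attempted" means the
  activity earned at least one frequency point.
* **Parent Engagement Intensity (PEI)** — intensity: over attempted
  activities, the sum of *frequency points × intensity factor*.

Both are standardized by their arm-specific maxima,

$$\mathrm{stdPPP} = \frac{\mathrm{PPP}}{|\text{offered}|}, \qquad
  \mathrm{stdPEI} = \frac{\mathrm{PEI}}{\sum_{a\,\in\,\text{offered}} \max w_a},$$

so every parent is measured on the fraction of *their own* opportunity set
taken, on a 0–100% scale. Parents at or above 75% of standardized PPP (or
PEI, by option) are classified **positive deviants** (PD) — the unusually
engaged subgroup whose activity profile is worth studying for transferable
engagement strategies.

## The intensity factor

Each activity's burden is summarized by five attributes, scored 0/1 and
summed to an **intensity factor** in 0–5:

| attribute | credit |
|---|---|
| not incentivized / unpaid | +1 |
| requires being away from home (internet-at-home counts as *not* away) | +1 |
| requires engaging the child | +1 |
| takes ≥ 30 minutes (0.5 h) per episode | +1 |
| requests personal information | +1 |

Two conventions deserve a note because the verbal rule alone is ambiguous:

* **The 30-minute boundary is inclusive** (`duration_hours >= 0.5` earns
  the point). Activities estimated at exactly 0.50 h carry the time credit
  in the canonical catalog, which fixes the convention.
* **Online activities done at home score 0** on the away-from-home
  attribute, even when they require substantial attention.

An intensity factor of 0 is possible for user-defined activities (paid,
at-home, childless, short, anonymous); `activity_type()` permits it but
warns, because such an activity can never contribute to the PEI. All eight
canonical activities have factors ≥ 1.

## Frequency points and weightings

Frequency points credit *how often* an activity was done. Three rule kinds
cover the canonical schema and user-defined ones:

* `per_occasion` — one point per occasion up to a maximum (surveys: up to
  3; online lessons: up to 6; evening events: up to 2; accelerometry: up
  to 3);
* `binned` — ranges of raw counts map to points (action packs: 1–3 → 1,
  4–6 → 2, 7–10 → 3; recipes: 1 → 1, 2–3 → 2, 4–5 → 3);
* `per_timepoint_binned` — a binned rule applied at each measurement
  timepoint and summed (diet assessments: at each of 3 timepoints, 1
  recall → 1, 2–3 recalls → 2).

Bins are validated at load time (start at 1, contiguous, non-overlapping,
non-decreasing points): silent mis-binning would corrupt every downstream
index, so a malformed catalog fails fast.

An activity's **maximum weighting** is its maximal frequency points times
its intensity factor. In the canonical eight-activity catalog every
weighting equals 6, a deliberate design symmetry: each activity type has
the same ceiling contribution to the PEI, so the arm maximum is simply
6 × (number of offered types). One consequence the package asserts as an
invariant: under the canonical catalog, standardized PEI can never exceed
standardized PPP.

A worked example (`fixture_table3()`, parent "example_C", offered 5
activities): 3 surveys (3 pts × 2) + youth diet assessments with 2 recalls
at each of 3 timepoints (6 pts × 1) + 1 online lesson (1 pt × 1) gives
PEI = 13 of a possible 30, stdPEI = 43.3%, and PPP = 3 of 5, stdPPP = 60%.

Two scoring footnotes:

* The schema's verbal description quotes a possible PEI range of 2–48, but
  under the rules as stated a single online lesson yields PEI 1; the
  package implements the rules, so the attainable range is 0–48 (0 for no
  participation).
* The full-menu worked example ("example_D") is sometimes quoted with a
  standardized PEI of 37.5%; that figure under-credits the action-pack
  contribution by omitting its intensity factor of 2. Scoring the stated
  counts under the stated rules gives (4+4+4+4+4)/48 = 41.7%, which is what
  the engine returns.

## Catalogs are data

The canonical schema — eight activities (four program: family fun nights,
action packs, recipe preparation, About Eating; four evaluation: parent
survey, parent and youth diet assessments, accelerometry) and 31
cohort × school arms — ships as a packaged JSON file loaded by
`build_default_catalogs()`. Users can define alternative schemas in the
same JSON shape and load them with `read_catalog_json()`; all structural
invariants are checked at load. One arm (cohort 4, school 5) does not exist
in the canonical design and its lookup raises an error rather than
inventing an empty arm.

## Records, validation, and scoring

Participation logs are tidy CSV: one row per parent × activity
(× timepoint), with raw counts. `validate_participation()` hard-errors on
an unknown arm (a mis-specified study layout) and *rejects* rows —
returning them with reasons — for unknown activities, activities not
offered in the parent's arm, and counts exceeding declared maxima after
aggregation. Accepted and rejected rows always partition the input.

`score_cohort()` scores every parent against their arm and joins outcome
records. Two retention rules reflect the intended analysis population:
parents appearing only in the outcomes table are kept with zero engagement
(youth without participating parents belong in comparisons), and parents
appearing only in the logs are kept with missing outcomes. Standardized
program/evaluation sub-scores are reported as missing — not zero — when the
arm offers no activity of that category, since the divisor is undefined.

`compute_score()` is the single-parent reference implementation;
`score_cohort()` is a vectorized equivalent, and the test suite asserts
element-wise equality between the two routes, plus equality with a
brute-force enumeration oracle written directly from the frequency scales.

## The analysis surface

The package reproduces the analysis toolkit such a study uses, as thin,
validated fronts over base R fits:

* `pearson_correlation()`, `two_group_t()` (pooled by default — the
  convention when variances are not suspected unequal; Welch by flag),
  `chi_square_independence()` (uncorrected Pearson χ²). Zero-variance
  groups return a degenerate statistic with a warning instead of aborting a
  batch of comparisons. **No multiple-testing correction is applied
  anywhere**; per-activity comparisons are reported at nominal levels, and
  users scanning many outcomes should adjust externally.
* `adjust_for_factors()` / `adjust_bmi_percentile()` — removes additive
  school and classroom effects (fixed-effects fit; residuals + grand
  mean). Classroom labels are treated as globally unique rather than
  nested codes; prefix labels if yours repeat across schools. The
  adjustment preserves the grand mean, removes the factor-coded
  between-group variance, and is idempotent.
* `repeated_measures_by_group()` — the two-timepoint (baseline vs
  12-month) split-plot decomposition: between-subject group effect,
  within-subject time effect, group × time interaction, with cell means
  and descriptive standard errors. The split-plot construction is the
  standard choice for a two-occasion repeated-measures GLM; with two
  timepoints it is equivalent to a t-test on change scores for the
  interaction. The intermediate (post-program) timepoint is available in
  summaries but deliberately outside this comparison.

The PD classification in reports defaults to the standardized **PPP**
basis, because the positive-deviance profile analyses are framed in terms
of breadth of participation; the basis is a parameter everywhere.

## The synthetic cohort generator

No study data ship with the package. `generate_cohort()` produces seeded
cohorts with exactly the structure the schema assumes:

* parents nested in the 31 arms with their unequal offerings;
* a latent engagement propensity θ ~ Beta(2, 2) per parent;
* per offered activity, an attempt with probability
  `plogis(qlogis(uptake_base) + propensity_scale·θ − burden_slope·intensity_factor)`,
  so burden suppresses uptake and propensity raises it;
* attempted activities draw raw counts uniformly over their valid values;
* youth baseline BMI percentile tied to θ through a Gaussian copula with
  correlation `bmi_dependence` and a normal marginal (mean 56.6, SD 30.1)
  clipped to (1, 99), with two follow-up timepoints drifting by
  `time_drift` plus small measurement noise.

The defaults (`uptake_base = 0.06`, `propensity_scale = 4.5`,
`burden_slope = 0.6`) were chosen once so the simulated margins resemble a
realistic cohort of this kind: roughly 55% of parents engage in at least
one activity, engaged parents average ~40% of their offered types and
~26% of their possible intensity, and ~10–13% of engaged parents reach the
PD threshold. Zero-engagement parents arise naturally when every attempt
fails — no special mechanism is needed to produce the large non-participant
group such studies see.

The copula targets a *rank* dependence between propensity and BMI
percentile; the product-moment correlation between *standardized PEI* and
BMI is attenuated relative to `bmi_dependence` (scoring is a noisy,
discretized readout of θ), so exact attainment of a target r is not
promised — sign and magnitude-ordering are, and those are what the tests
assert.

What the generator does **not** emulate: psychosocial covariates,
demographic structure, survey-gated consent (in real designs some
activities require survey completion first, creating dependence between
activities beyond the shared θ), attrition, and within-family clustering.
Passing tests on synthetic cohorts therefore validate the *scoring and
analysis machinery*, not substantive claims about any real population.

## Numerical and design choices

* Standardized indices are stored as fractions in \[0, 1\]; rendering as
  percent multiplies by 100.
* The PD boundary is inclusive (≥ 0.75), and thresholds outside (0, 1\]
  are rejected.
* Per-occasion counts split across rows are summed before the
  maximum-count check; binned activities are binned on the aggregated
  total.
* A survey timepoint counts as completed if any completion evidence is
  logged (a row with a positive count); partial completions are not
  further graded.
* Problem sizes in the shipped test suite: oracle equivalence on 1,000
  randomly generated parents; type-I-error calibration of the t-test on
  2,000 null replicates; dependence-sign recovery on 200 simulated cohorts
  of ~500 parents (16 per arm). These sizes give Monte-Carlo error well
  inside the asserted bounds while keeping the default test run fast.

## Limitations

* The intensity factor is an equal-weight sum of five binary burden cues;
  it is a transparent ordinal device, not an estimated utility.
* Arm-standardization makes scores comparable as *fractions of
  opportunity*, which is not the same as equal behavioral cost across
  arms: 100% of one offered survey is a smaller commitment than 100% of
  eight activities.
* The engagement–outcome analyses are observational associations;
  engagement is self-selected and nothing here supports causal reading.
* Longitudinal change in engagement intensity is out of scope; scores
  summarize a whole study cycle.
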
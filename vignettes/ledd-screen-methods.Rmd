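---
title: "Screening drugs for slower Parkinson's progression with claims data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drugs for slower Parkinson's progression with claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leddscreen)
```

## The question and the surrogate outcome

Parkinson's disease (PD) has no registry-recorded severity score, but almost
every treated patient leaves a dense trail of prescriptions. Because
dopaminergic medication is titrated against symptoms, the **levodopa
equivalent daily dose (LEDD)** — the sum of each PD drug's daily dose times
its published levodopa-equivalence factor — rises as the disease progresses
and is widely used as a progression surrogate. `leddscreen` implements a
pharmacoepidemiological screen over that surrogate: for a candidate drug
class (the shipped configuration screens 15 H1-antihistamines), compare how
fast LEDD rises in patients exposed to the candidate versus matched
unexposed PD patients. A drug whose exposed group shows a *smaller* LEDD
increment is a repurposing signal worth wet-lab follow-up.

The outcome statistic is the **increment ratio**

$$\mathrm{IR} = 100 \times \frac{1}{N}\sum_{i=1}^{N}
\frac{\mathrm{LEDD}_{\mathrm{after},i}-\mathrm{LEDD}_{\mathrm{before},i}}
     {\mathrm{LEDD}_{\mathrm{before},i}},$$

the mean over patients of each patient's percent LEDD change from the 90
days before to the 90 days after an index date. This mean-of-ratios weights
every patient equally regardless of dose level; it is *not* the percent
change of the group-mean LEDD, and the package computes the two through
separate code paths (`increment_ratio()` vs `aggregate_ratio()`) because the
two only agree when all baselines are equal. Patients with a zero pre-index
LEDD have an undefined ratio; they are excluded from the mean and reported
as a count — the only definition-preserving choice.

## Pipeline stages

1. **Load and validate** (`read_claims()`): typed patient / prescription /
   drug tables; malformed values are errors with a column and line number;
   rows with a *missing* period, daily dose, or single dose are flagged,
   never silently dropped.
2. **Inclusion/exclusion** (`apply_exclusions()`), in a fixed order with an
   attrition log: diagnosis at age ≥ 40; at least one PD-drug or
   antihistamine prescription; no invalid prescription row (one bad row
   excludes the patient, matching how registries quote patient-level
   exclusion counts). The order of the first and last rule is a convention;
   the log makes it auditable.
3. **Exposure episodes** (`build_episodes()`): prescriptions of one drug
   merge into a continuous episode when the gap from the previous coverage
   end (date + period, half-open) to the next start is under 31 days;
   an episode qualifies as exposure when its span strictly exceeds 31 days.
   Gap-from-coverage-end is the pharmacoepidemiology standard reading of
   "two prescriptions within a month"; start-to-start is available via
   `gap_basis = "start"`.
4. **Classification** (`classify_patients()`): exposed = at least one
   qualifying episode and exactly one distinct antihistamine across all
   antihistamine prescriptions; qualifying multi-antihistamine users are
   excluded (not returned to the control pool — the conservative reading);
   everyone else retained is unexposed.
5. **Index dates** (`assign_index_dates()`): exposed patients anchor at the
   first prescription of their first *qualifying* episode (the literal
   first-ever antihistamine prescription is available via
   `index_mode = "first_ever"`; it can differ when an early short run
   precedes the qualifying one). The median diagnosis-to-index interval of
   the exposed group is then added to each unexposed patient's diagnosis
   date, transferring the exposed group's timeframe. Per-drug screens use
   per-drug medians; the overall screen uses the overall median. Patients
   whose 90-day windows leave the observed horizon are flagged and skipped.
6. **LEDD windows** (`ledd_window()`): time-averaged daily LED over the
   half-open windows `[index-90, index)` and `[index, index+90)`, with
   pro-rata contribution of prescriptions spanning a window edge. "Three
   months" is fixed at 90 days — calendar months are not reproducible across
   index dates. The registry description of LEDD (LED × prescription period)
   is a cumulative quantity, but published group values sit on a daily-dose
   scale; the daily average (cumulative LED-days / 90) reconciles both, and
   `cumulative = TRUE` reports the raw sum. Conversion factors are data, not
   code: a packaged CSV (levodopa 1.0, pramipexole 100, ropinirole 20,
   rasagiline 100, selegiline 10, amantadine 1.0; entacapone as 0.33 × the
   concurrent levodopa LED; decarboxylase inhibitors contribute nothing) that
   can be replaced wholesale.
7. **Propensity matching** (`fit_propensity()`, `nearest_neighbor_match()`):
   logistic regression of exposure on sex, age at diagnosis, cumulative
   pre-index PD-drug coverage days, and pre-index window LEDD; greedy 1:3
   nearest-neighbour matching without replacement, processing exposed
   patients in descending score order (ties by patient id), with a caliper
   of 0.25 × SD of the pooled scores — the convention of the standard
   matching software; absolute-probability units are available. Distances
   are on the probability scale (configurable ambition left to the user:
   the logit scale is a one-line change in the score vector). In strict mode
   an exposed patient who cannot fill all three slots inside the caliper is
   dropped and its provisionally taken controls return to the pool, so
   `controls = 3 × retained exposed` holds exactly. Separation or
   non-convergence triggers a warning and a lightly ridge-penalised fallback
   fit.
8. **Comparison** (`increment_ratio()`, `compare_groups()`): two-sided
   unpaired t-test on the per-patient ratios; Welch by default (the safer
   default under unequal variances), Student's pooled test optional.
   Degenerate inputs are defined, not crashed: two identical constant
   samples give t = 0, p = 1. No multiplicity adjustment by default,
   mirroring how such screens report raw per-drug p-values;
   Benjamini–Hochberg is one switch away (`adjust_pvalues()`).

`run_screen()` chains all stages and emits one report row per scope
(overall, 1st/2nd antihistamine generation, each drug), with the attrition
log, group assignments, and per-row balance diagnostics attached as
attributes. Scopes with too few exposed patients are reported as skipped,
not failed.

## The synthetic claims generator

Real national-registry claims cannot be redistributed, so the package ships
a generator (`generate_population()`) that reproduces the *statistical
structure* the screen relies on, with known ground truth:

- **Latent severity** $z \sim N(0,1)$ drives baseline LEDD
  ($250 \pm 50$ mg/day by default, floored at 50), partially drives the
  progression rate (correlation 0.3), and — through a logistic link with
  slope `confounding_strength` — the probability of exposure. With positive
  confounding, sicker patients are both more exposed and faster-progressing,
  so the naive comparison is biased and matching has real work to do.
- **Dose trajectories** are piecewise-constant over 90-day blocks and
  compound by `progression_per_window_mean` $\pm$ sd percent per block
  (9 ± 15 by default; negative draws — dose reductions — are allowed, and
  the series is floored at zero). Exposure multiplies the post-anchor
  increment by `1 - exposure_effect`.
- **Anchoring.** Each patient's trajectory carries its baseline in the 90
  days just before the point where the screen will measure it: the patient's
  own first-antihistamine date for observably-exposed patients, and
  diagnosis + (median exposed interval) for everyone else. The
  `baseline_ledd_*` parameters therefore describe dose levels *at the index
  date* — the scale on which screen reports state group means — and, under
  the null, both groups' measured increment ratios reduce to the patient's
  own progression draw, which makes the calibration experiments sharp.
  Patients whose assigned exposure is truncated by the study horizon (never
  observable) are treated as unexposed throughout.
- **Dispensing realism.** PD medication is dispensed in ~30-day refills
  (one of five PD drugs per patient, dosed so the levodopa-equivalent
  realises the latent trajectory) with a 0–90-day therapy start delay, small
  Poisson refill slippage, and, for ~60% of patients, one longer therapy
  interruption (30–400 days). The interruption is always placed so that
  coverage has resumed at least one refill cycle before the pre-index
  window: treatment histories vary across patients (which the propensity
  model needs — otherwise pre-index coverage is a near-constant in the
  control group and degenerates into a group separator), while the outcome
  windows remain fully observed. Real interruptions also overlap measurement
  windows and would add outcome noise; passing tests therefore speak to the
  pipeline's correctness under clean peri-index coverage, not to robustness
  against mid-window treatment gaps.
- **Antihistamine refills** for exposed patients start at the anchor with
  two refills inside a month (so assigned exposure qualifies under the
  31-day rules), then continue with a mixture of short (< 31-day,
  continuity-preserving) and long gaps. Intervals from diagnosis to anchor
  are log-normal with a median near 752 days — the scale reported for the
  source cohort — with a 182-day floor so the pre-index window lies inside
  the treated period. A configurable fraction of users (5%) receives a
  second distinct antihistamine; 10% of the unexposed get one short,
  non-qualifying antihistamine prescription.
- **Corruption.** A configurable fraction of prescription rows (2%) has one
  of period / daily dose / single dose blanked. Hits are clustered within
  "missingness-prone" patients (15% of a prone patient's rows) rather than
  sprinkled independently: the expected row fraction is unchanged, but
  patient-level attrition stays registry-like (~13% of patients) instead of
  the near-total attrition independent corruption would cause at ~60 rows
  per patient. About 1% of patients are generated deliberately invalid
  (diagnosed under 40, or without any prescription) to exercise the
  exclusion rules.

## Study conditions for the simulation experiments

The package's statistical guarantees are demonstrated by two experiments
(run in full by the acceptance suite, at reduced size by
`analysis/03_operating_characteristics.R`):

- **Null calibration** — 200 replicates of 2,000 patients with
  `exposure_effect = 0` and otherwise default parameters. The screen's
  p-values should be uniform (Kolmogorov–Smirnov test) with type-I error
  near 0.05.
- **Confounded-effect recovery** — 20 replicates of 5,000 patients with
  `exposure_effect = 0.5`, `confounding_strength = 0.5`, and exposure
  prevalence 0.15. The matched analysis should report a significantly lower
  exposed increment ratio in ≥ 90% of replicates, with all post-match
  standardized mean differences ≤ 0.1 while the unmatched comparison is
  visibly imbalanced. Prevalence is set to 0.15 here (the generator's
  default is 0.25) so the control pool is several times deeper than the
  3-per-exposed minimum that 1:3 matching without replacement consumes; the
  source cohort had roughly twelve unexposed patients per exposed one, and
  strict 1:3 matching is not meaningfully possible when the pool barely
  covers the demand.

Replicate sizes (2,000/5,000 patients; 200/20 replicates) are the sizes at
which these properties are stated and tested; they keep a full desk run in
the minutes range while leaving Monte-Carlo error well below the margins
being asserted.

## Numerical and degenerate-case choices

- Dates are integer day offsets from a study epoch; all coverage intervals
  are half-open, so adjacency and overlap are unambiguous.
- Episode merging uses a running coverage maximum, so overlapping refills
  (early dispensing) union correctly; merging is order-independent.
- The matcher resolves control-distance ties to the lower sorted index
  (after sorting controls by score then id), making the whole screen
  deterministic end to end: one seed, one byte-identical report.
- A caliper on a zero-variance score degrades to machine epsilon rather
  than zero, so degenerate inputs drop unmatched units instead of erroring.
- `compare_groups()` defines p = 1 for two identical constant samples and
  refuses groups of fewer than two ratios.
- The worked boundary cases of the exposure rules: a gap of exactly 31 days
  starts a new episode ("less than one month" is strict) and a 31-day span
  does not qualify ("exceeding one month" is strict).

## Known limitations

- The generator does not model diagnosis-code noise, death or censoring,
  pharmacy-level dispensing idiosyncrasies, dose–response in the exposure,
  or treatment gaps overlapping the measurement windows; conclusions from
  synthetic runs are about pipeline correctness, not clinical effect sizes.
- LEDD is an indirect surrogate: dose decisions also reflect prescriber
  habits and tolerability, which the screen cannot separate from
  progression.
- Greedy nearest-neighbour matching is order-dependent by construction;
  optimal/full matching and weighting approaches are out of scope.
- The published per-drug results of the source cohort are not reproducible
  here because those claims data are not public; the package reproduces the
  *method* and validates it on data with known truth.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(n_patients = 5000, seed = 1,
                         exposure_effect = 0.5, confounding_strength = 0.5,
                         exposure_prevalence = 0.15)
pop <- generate_population(cfg)
report <- run_screen(pop, scope = "overall", verbose = TRUE)
print(report)
```
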
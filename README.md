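# leddscreen

Drug-repurposing screens over prescription-claims data, using the levodopa
equivalent daily dose (LEDD) as a Parkinson's disease (PD) progression
surrogate.

## The problem

PD severity is not recorded in insurance claims, but dopaminergic medication
is titrated against symptoms, so the total daily dose — expressed in
milligrams of levodopa equivalents (LEDD) — drifts upward as the disease
progresses. If exposure to some unrelated, already-marketed drug slows
progression, the LEDD of exposed patients should rise more slowly than that
of comparable unexposed patients. `leddscreen` turns that idea into a tested
pipeline for claims-style tables: it is written for pharmacoepidemiologists
who want to run, audit, or stress-test such a screen without access to the
original registry, and it ships a synthetic-claims generator with known
ground truth so every stage is verifiable.

The shipped configuration screens 15 H1-antihistamines against PD
progression; the drug table (codes, classes, antihistamine generations, LED
conversion rules) is data, not code, and can be replaced.

## The statistic

For each drug, patients with a qualifying continuous exposure episode
(refill gaps under 31 days, total span over 31 days, a single antihistamine
agent) are indexed at their first qualifying prescription; unexposed
patients are indexed at their diagnosis date plus the exposed group's median
diagnosis-to-exposure interval. After 1:3 propensity-score
nearest-neighbour matching (logistic model on sex, age at diagnosis,
pre-index PD-drug coverage days, and pre-index LEDD; caliper 0.25 SD of the
score; without replacement), the groups are compared on the increment ratio

IR = 100 × (1/N) Σᵢ (LEDD_after,i − LEDD_before,i) / LEDD_before,i

where the before/after values are time-averaged daily LEDD over the 90 days
each side of the index date. A smaller increment ratio means slower apparent
progression. Groups are compared with a two-sided unpaired t-test (Welch by
default) on the per-patient ratios.

## Worked example

Simulate a confounded cohort in which exposure truly halves the progression
increment, and screen it:

```r
library(leddscreen)
cfg <- simulation_config(n_patients = 5000, seed = 1,
                         exposure_effect = 0.5, confounding_strength = 0.5,
                         exposure_prevalence = 0.15)
pop <- generate_population(cfg)
report <- run_screen(pop, scope = "overall", verbose = TRUE)
print(report)
```

```
input: 5000 patients, 240053 prescription rows
  input                                removed      0 remaining   5000
  diagnosed_at_or_after_age_40         removed     19 remaining   4981
  has_pd_drug_or_antihistamine_rx      removed     19 remaining   4962
  no_missing_prescription_fields       removed    681 remaining   4281
groups: 610 exposed, 3639 unexposed, 32 multi-antihistamine excluded
LEDD increment-ratio screen
    drug exposed_n exposed_n_matched unexposed_ledd_before unexposed_ledd_after
 Overall       610               566               247.812              275.362
 unexposed_difference unexposed_ratio exposed_ledd_before exposed_ledd_after
                27.55          10.493             249.193            265.513
 exposed_difference exposed_ratio p_value
             16.321         6.297       0
```

Reading the row: 610 exposed patients survived the exclusion and exposure
rules; 566 of them found three caliper-eligible controls. The matched
unexposed group's LEDD rose from 247.8 to 275.4 mg/day (mean per-patient
increment ratio 10.5%), the exposed group's from 249.2 to 265.5 (6.3%) —
close to the simulated halving of the ~9%-per-window progression after
attenuation by refill carry-over — and the difference is highly significant
(the printed p rounds to 0). The attrition log mirrors the flow-diagram
counts a registry study would report.

The same pipeline runs as a three-step analysis:

```sh
Rscript analysis/01_simulate.R --n 12000 --seed 42 --effect 0.5 \
    --confounding 0.5 --prevalence 0.15
Rscript analysis/02_screen.R           # overall + generations + per drug
Rscript analysis/03_operating_characteristics.R
```

Step 2 writes `results/screen_report.csv` (one row per drug in the published
table's layout), `results/attrition.csv`, and `results/balance.csv`.

## Scope

The original registry extract is not public, so published per-drug results
are not reproducible here; the package reproduces the method and validates
it on synthetic data with known truth. Survival modelling, dose–response
analyses, and optimal matching are out of scope. See
`vignettes/ledd-screen-methods.Rmd` for the full methods account.
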
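# thyropd

Pharmacodynamic modelling of the thyroid-hormone response to carbimazole
in Graves' hyperthyroidism.

Graves' disease is the commonest cause of hyperthyroidism, and carbimazole
dose titration is its usual first-line therapy, yet little quantitative
guidance links the dose to the resulting fall in free thyroxine (fT4) and
free triiodothyronine (fT3). `thyropd` is an analysis pipeline built
around a discrete-time daily drug-effect recursion

```
fT4(n+1) = fT4(n) − (m · Dose^p · fT4(n) + c)
```

with phase-specific coefficients (the first inter-visit interval shows a
larger per-dose fall than later ones), fitted from the percentage fall in
hormone level per day across clinic-visit intervals of at least 21 days.
Around that core the package provides:

* **cohort handling** — a validated two-table CSV schema (patients,
  visits), thyroid-status classification (hyperthyroid / euthyroid /
  overtreated / indeterminate) against standard reference ranges;
* **baseline analysis** — day-0 regressions of hormones on TSH-receptor
  antibody titre and of fT3 on fT4, and the coupling of daily fT3 falls
  to fT4 falls;
* **dose-response lines** — per-dose median percentage fall per day
  versus dose, by hormone and phase, with the 21-day interval filter;
* **the PD model** — forward simulation, conversion of lines to recursion
  coefficients, dose-exponent and body-weight refinements assessed by
  one-step RMSE, and inverse use: the lowest dose in the clinical set
  that reaches a target fT4 within a monitoring horizon;
* **relapse analysis** — subgroup relapse rates, odds ratios (Woolf CIs,
  Haldane–Anscombe zero-cell correction), multivariable logistic
  adjustment, overtreatment frequency, and an additive Relapse Rate
  Score stratified at <15 / 15–20 / >20;
* **a calibrated synthetic cohort generator** — since no patient-level
  dataset is deposited, every published summary statistic the analysis
  rests on (baseline distributions, dose-response lines, fall coupling,
  subgroup relapse rates, model RMSE) is embedded in the generator as
  recoverable ground truth, so the whole pipeline is testable end to end.

The methods vignette (`vignettes/thyropd-methods.Rmd`) documents the
model, the calibration choices and their limitations.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
generated 441-patient cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # generate + serialise the cohort
Rscript analysis/02_baseline.R      # baseline regressions
Rscript analysis/03_dose_response.R # %fall/day lines by dose and phase
Rscript analysis/04_pd_model.R      # recursion fit, RMSE, dose advice
Rscript analysis/05_relapse.R       # relapse stratification
```

Selected output from one run (seed 42):

```
baseline: mean fT4 32.9 pmol/L, mean fT3 19.0 pmol/L, median TSHRab 3.84 U/mL
  fT3 ~ fT4:       slope 0.905, intercept -10.74, r2 0.70
  ft4 initial   %fall/day = 0.040*dose +0.087  (r2 0.99)
  ft4 followup  %fall/day = 0.032*dose -0.169  (r2 1.00)
ft4: one-step RMSE 4.11 pmol/L; dose exponent 1.14
recommendation: fT4 45 -> <=23 pmol/L in 42 d: 40 mg/day (reaches target on day 40)
  stratum   n relapse_pct
1     <15 101     9.90099
2   15-20 307    36.48208
3     >20  33    81.81818
top vs bottom stratum: OR 41.0 (95% CI 13.6-123.0)
```

Reading this: baseline fT3 tracks fT4 almost 1:1 (slope ≈ 0.9 pmol/L per
pmol/L); during the initiation interval each additional 10 mg of
carbimazole buys ≈0.4 percentage points of fT4 fall per day, and the same
dose is roughly 25% less effective at follow-up; the fitted recursion
predicts next-visit fT4 to ≈4 pmol/L; a patient presenting at
45 pmol/L needs the maximum 40 mg/day to be in range within six weeks;
and the relapse score separates a low-risk tail (≈10% relapse) from a
high-risk tail (≈80%) after treatment withdrawal.

A quick interactive session:

```r
library(thyropd)
ch  <- generate_cohort(generator_config(seed = 1))
iv  <- build_intervals(ch)
fit_dose_response(iv, "ft4", "initial")
#> initial ft4: %fall/day = 0.03864 * dose +0.1539  (r2 = 1.000, 441 intervals)
prm <- fit_linear_params(iv, "ft4")
recommend_dose(42, 23, 42, prm, phase = "initial")
#> $dose_mg [1] 40  $reachable [1] TRUE  $days_to_target [1] 36
```

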
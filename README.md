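# playEE

Estimating free-living energy expenditure (EE) of preschool-aged children
(3–5 y) from raw tri-axial accelerometry, calibrated against portable
indirect calorimetry during free play.

Activity energy expenditure in young children is usually predicted from
accelerometer "counts" calibrated in laboratory protocols, which transfer
poorly to the sporadic, short-burst activity of real free play. This package
implements the full calibration pipeline for free-living data — from
breath-by-breath gas exchange and 100 Hz raw acceleration to
cross-validated machine-learning predictors and agreement statistics — as a
reusable, tested R package plus a set of numbered analysis drivers. Because
no public dataset of paired calorimetry/accelerometry for this age group
exists, the package ships a seeded synthetic-session generator with a known
activity→EE mapping, so every downstream stage is testable end to end and
parameter-recovery claims can be checked against planted ground truth.

Audience: researchers in physical-activity measurement, wearable-sensor
methods and paediatric exercise physiology who want a transparent,
reproducible reference implementation of this calibration design.

## What the pipeline computes

* **Criterion EE.** Breath-by-breath VO₂/VCO₂ are averaged in 10 s bins,
  smoothed with a centred 60 s moving average, and converted with the
  abbreviated Weir equation

  EE (kcal·min⁻¹) = 3.941·VO₂ + 1.106·VCO₂  (VO₂, VCO₂ in L·min⁻¹).

  MET values divide EE by resting EE predicted from Schofield's
  weight-and-height equations for children aged 3–10 y
  (male: BMR = 0.082·W + 0.545·H + 1.736 MJ·day⁻¹; female:
  0.071·W + 0.677·H + 1.553; W in kg, H in m).
* **Features.** Each 100 Hz recording (hip and non-dominant wrist) is
  segmented into non-overlapping 10 s windows; 118 time- and
  frequency-domain features are extracted per axis and vector magnitude
  (moments, percentiles, crossings, activation-run statistics on the
  rectified 5 Hz-lowpass-filtered signal, dominant frequency/magnitude in
  0.25–5 Hz, cross-axis correlations, orientation angles) and matched to
  the criterion by window start time.
* **Feature selection.** Greedy minimum-redundancy maximum-relevance
  (mRMR) against the continuous EE target, constrained to the 10/15/20
  best features: relevance is the univariate regression F statistic and a
  candidate's step score is F·(1 − R²), with R its largest absolute
  correlation with the already-selected set.
* **Models.** Random forest (500 trees, 3 features per split), RBF-kernel
  support-vector regression (cost 6.0, γ 0.1) and a single-hidden-layer
  neural network (11 neurons, weight decay 0.1), for hip and wrist, in a
  free-living arm (fold-nested mRMR) and a retrained-laboratory arm (the
  laboratory architectures refit on free-living windows). Evaluation is
  leave-one-subject-out cross-validation (LOSO-CV) plus a disjoint
  10-child hold-out sample.
* **Agreement battery.** Per-subject RMSE (kcal·min⁻¹ and METs) and MAPE;
  one-way repeated-measures ANOVA across models with Fisher LSD post hoc;
  Bland–Altman mean bias and 95% limits of agreement on session totals,
  with proportional-bias regression and magnitude-specific prediction
  limits.

## Worked example

```r
library(playEE)

# four children, 10-minute sessions, hip accelerometer
cohort <- make_cohort(4, seed = 1)
sessions <- synthesize_cohort(cohort, seed = 2, session_length = 600)
tab <- cohort_feature_table(sessions, sites = "hip")

# five most informative, least redundant features
cand <- intersect(feature_catalog(), names(tab))
mrmr_select(tab[, cand], tab$ee_kcal_min, k = 5)
#> mRMR selection of 5 features:
#>  1. x_p90 (score 2.13e+03)
#>  2. x_logenergy (score 133)
#>  3. y_min (score 124)
#>  4. y_mcross (score 110)
#>  5. y_dommag (score 109)

# leave-one-subject-out random forest
res <- loso_cv(model_config("rf", "hip", "free_living",
                            k_features = 10, seed = 3), tab)
res$per_subject
#>   participant_id rmse_kcal rmse_met mape n_windows
#> 1           P001     0.150    0.257 5.28        60
#> 2           P002     0.212    0.366 9.51        60
#> 3           P003     0.179    0.286 6.62        60
#> 4           P004     0.190    0.309 8.66        60
```

The per-subject rows say: predicting the held-out child's 10 s EE from hip
movement alone leaves a root-mean-square error of 0.15–0.21 kcal·min⁻¹
(0.26–0.37 METs), i.e. a mean absolute percent error of 5–10% of the
measured value. The calorimetry primitives are available directly:

```r
ree <- schofield_ree("male", 1.05, 17)   # 884.9 kcal/day = 0.6145 kcal/min
weir_ee(0.30, 0.26)                      # 1.4699 kcal/min
to_mets(weir_ee(0.30, 0.26), ree)        # 2.39 METs
```

## Analysis workflow

The `analysis/` scripts replay the full study design in order, writing all
tables under `results/`:

| script | stage |
| --- | --- |
| `01_simulate.R` | 25-child cohort (15 train / 10 hold-out), 20-min sessions, manifest + example raw CSVs |
| `02_calorimetry.R` | criterion EE series per child, session totals |
| `03_features.R` | labeled 10 s feature tables, both wear sites |
| `04_select.R` | mRMR reports for k = 10, 15, 20 per site |
| `05_models_loso.R` | LOSO-CV of the eight model arms (~15 min) |
| `06_evaluate.R` | hold-out metrics, RM-ANOVA + Fisher LSD, Bland–Altman |

Each script is deterministic given the master seed in
`analysis/00_config.R`. A single call to `run_pipeline(run_config(seed))`
executes the same stages programmatically.

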
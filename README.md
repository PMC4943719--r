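# dietscores

Diet-quality scores and 10-year mortality prediction in multi-center cohorts.

`dietscores` is an R package for nutritional epidemiologists who want to
compute a-priori diet-quality indices from individual-level intake tables and
evaluate how well those indices predict mortality. It implements ten widely
used scores — HEI-2010, DQI-I, WHO Healthy Diet Indicator, Healthy Lifestyle
Index (HLI), WCRF/AICR guideline score, DASH, Mediterranean Diet Score (MDS),
relative Mediterranean score (rMED), Mediterranean Style Dietary Pattern
Score (MSDPS) and the Healthy Nordic Food Index (HNFI) — including all the
population-dependent cut-off machinery the indices require (sex-specific
medians, tertiles and quintiles; center-specific deciles), and the modified
sodium-free variants used when sodium intake is unavailable (DASH 7–35,
DQI-I 0–94, HEI-2010 0–90).

Around the scoring engine the package provides the full evaluation pipeline:

- **Association**: Cox proportional-hazards models stratified by sex and
  study center, with the score entered per standard deviation
  (standardized within sex × center) or by sex- and center-specific
  quartiles with a linear trend test. Model 1 adjusts for age; Model 2 adds
  BMI, smoking, physical activity and education (reduced sets for HLI and
  WCRF, whose components already include lifestyle; optional energy
  adjustment). Follow-up is truncated at 10 years; cause-specific analyses
  (CVD, cancer, obesity-related cancer) censor competing deaths.
- **Discrimination**: Harrell's C-statistic for censored survival,
  `C = (concordant + 0.5·tied) / usable pairs`, where a pair is usable iff
  the smaller follow-up time carries an event, with delta-C against an
  age-only baseline model.
- **Calibration**: 10-year absolute risk from the per-stratum Breslow
  baseline, `risk = 1 − exp(−H₀(10)·e^lp)`, observed risk per decile of
  predicted risk via Kaplan–Meier, predicted-to-observed ratios, and the
  calibration slope (Cox refit coefficient of the linear predictor).
- **Between-country heterogeneity**: per-country fits pooled by
  DerSimonian–Laird random-effects meta-analysis with Cochran's Q and I².
- **Synthetic cohorts**: a generator emulating a pan-European cohort
  (10 countries / 23 centers, sex-specific covariates and correlated
  log-normal intakes, nutrients derived from a food-composition table,
  cause-specific Weibull proportional hazards with competing causes and
  per-center administrative censoring) with a stored latent diet-quality
  factor, so every stage can be validated against known ground truth.

## Worked example

```r
library(dietscores)

cc     <- cohort_config(n_subjects = 50000, seed = 42)
cohort <- apply_exclusions(generate_cohort(cc))   # drops prevalent disease
scores <- score_all(cohort)                        # all ten indices

ad   <- prepare_analysis_data(cohort, scores, outcome = "all_cause",
                              score_cols = c("mds", "dash"))
fit2 <- fit_model(ad, model_spec("all_cause", "mds", model = 2))
round(fit2$per_sd, 3)
#>     hr    lcl    ucl  loghr     se      p
#>  0.933  0.887  0.983 -0.069  0.026  0.009
```

A one-SD increase in MDS is associated with a 6.7% lower 10-year all-cause
mortality hazard in this simulated cohort (the generator's latent
diet-quality factor is protective by default, and MDS captures part of it).
Discrimination and calibration of the full model:

```r
base <- fit_model(ad, model_spec("all_cause", NULL, model = 1))
compare_models(base, fit2)$delta            # delta C vs age-only baseline
#> C (Model 2) = 0.742, delta = 0.0225

pred <- predict_10y_risk(fit2)
cal  <- calibration_table(pred, ad$time, ad$event, strata = pred$stratum)
#> overall predicted/observed = 0.999, calibration slope = 1.000
```

Quartile HRs show the dose–response shape (Q1 reference; HRs 0.98, 0.94,
0.84 for Q2–Q4, p-trend 0.015 in this run), and country-level pooling gives
`pooled HR 0.933 (0.886–0.983), I² = 0%`. `run_pipeline(run_config(...))`
executes the whole chain — simulate, score, prepare, fit, evaluate, pool —
and writes tidy CSV tables plus a manifest with the seed and configuration
hash.

All scoring thresholds (guideline targets, serving sizes, recommended
intakes, the composition table) live in
`inst/extdata/score_config.yaml`; load with `default_score_config()`,
modify, and pass via the `config` argument.

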
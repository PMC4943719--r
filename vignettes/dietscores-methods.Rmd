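---
title: "Methods: scoring systems, survival models and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring systems, survival models and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific choices behind `dietscores`: how each
diet-quality index is operationalized, how the survival and prediction
machinery is defined, what the synthetic cohort generator does and does not
emulate, and the numerical conventions that make results reproducible.

## The ten indices

Scores split into three cut-off families.

**Predefined cut-offs** (computable per subject in isolation):

* *WHO HDI* (0–7): one point per component inside a guideline range —
  SFA 0–10%E, PUFA 3–7%E, protein 10–15%E, cholesterol 0–300 mg/d, fibre
  25–40 g/d, fruit + vegetables ≥ 400 g/d, free sugars 0–10%E. Percent of
  energy uses 9/4/4/7 kcal per gram of fat / protein / carbohydrate /
  ethanol throughout the package. The ranges are configuration, because
  different guideline editions print slightly different numbers.
* *HEI-2010* (modified, 0–90): density scoring per 1000 kcal with linear
  proration between a minimum and maximum standard per component, reverse
  scoring for the moderation components. With sodium unavailable, the
  10-point sodium row is removed; the published 100-point total therefore
  becomes 90 in the default configuration. (A 95-point variant can be
  encoded by editing the YAML if a user wants to match a different
  modification; 90 is what removing one 10-point component from 100
  arithmetically yields.)
* *DQI-I* (modified, 0–94): variety (overall 0–15 at 3 points per major
  food group reaching one serving/day, protein-source variety 0–5),
  adequacy (8 × 0–5 at full/half targets), moderation (4 × 0–6 after
  removing the sodium row from the published five), and balance
  (macronutrient ratio 0–6, fatty-acid ratio 0–4). Serving sizes and
  targets are gram-based adaptations of the original servings, shipped as
  configuration.
* *MSDPS* (≤ 100, negatives possible): thirteen components scored
  `10 × intake/recommended` up to the recommendation; over-consumption is
  deducted linearly in the relative excess (`10 − 10 × (ratio − 1)`), the
  proration implied by "60% of the recommendation scores 6". The total is
  `(Σ components / 130) × 100` weighted by the fraction of energy from
  Mediterranean-pyramid foods (capped at 1; per-gram food energies come
  from the shared composition table).

**Sex-specific population cut-offs**: *MDS* (0–9, medians; the MUFA:SFA
component also uses the sex-specific median, consistent with the other
components), *rMED* (0–18, tertiles scored 0/1/2 with meat and dairy
reversed; olive oil 0 for non-consumption, 1 below / 2 at-or-above the
consumer median), *HNFI* (0–6, medians), *DASH* (modified 7–35,
quintiles scored 1–5, sweet beverages and red/processed meat reversed).
Two of these indices declare more components than they list rules for;
the defaults follow the original index publications: rMED's ninth
component is alcohol scored 0/2 inside the moderate window (10–50 g/d men,
5–25 g/d women, the same window MDS uses), and HNFI's sixth food is
whole-grain cereals (oatmeal). Both are configuration.

**Center-specific cut-offs**: *HLI* ranks seven diet components into
center-specific deciles scored 0–9 (margarine and glycaemic load
reversed; 0–63 total), then awards 0–4 graded points each for smoking,
alcohol, physical activity, BMI and the cohort-wide quintile of the diet
score (0–20 total). The published description of the health index is
ambiguous between binary and graded 4-point components; the default is a
documented graded mapping (e.g. never/former/current smoking → 4/2/0),
and a binary 0/4 mapping can be encoded in the YAML. *WCRF/AICR* scores
each recommendation 1 / 0.5 / 0 (sub-components averaged), 0–7 for women
(breastfeeding included) and 0–6 for men.

Missing components are a hard error by default — a score computed from a
subset of its components is not the same score. The sodium-style
"rescale to the available maximum" policy is what the modified
DASH/DQI-I/HEI configurations implement explicitly.

## Cut-off conventions

All population-dependent boundaries are linear-interpolation sample
quantiles (R type 7), fixed so that sort-based oracles reproduce them
exactly. A value **at** a boundary is assigned to the **higher** bin —
the deterministic reading of "above the median" scoring. A stratum in
which a component is constant has no usable quantiles; the package warns
and assigns all its subjects the lowest bin, a conservative deterministic
fallback (this also covers the all-tied quartile case).

## Survival analysis

Follow-up is truncated at 10 years (later events censored at 10);
cause-specific analyses censor competing deaths at the death time.
Scores are standardized (sample SD, denominator n − 1) and quartiled
within sex × center. Cox models are stratified by sex and center and use
the Efron tie approximation by default (event times are continuous here,
so the choice is inert; Breslow is a flag). The quartile trend test
enters the quartile index 1–4 as a single continuous term and reports its
Wald p-value — the most common convention where the original analysis
does not state one; quartile-median coding would be a one-line variant.
Listwise deletion handles missing covariates, with counts logged.

Harrell's C uses the usable-pair definition (the smaller time must carry
an event; tied times are unusable) with tied predictions counted half.
The standard error is a grouped (delete-a-group, 10 groups) jackknife
over subjects — cheap at any n and configurable — since no analytic
estimator is prescribed. Ten-year risks come from the per-stratum Breslow
baseline cumulative hazard evaluated on the fit's own data (apparent
performance, matching the reported analysis; k-fold validation can be
layered on top by refitting). Calibration bins subjects by deciles of
predicted risk, takes observed risk as 1 − KM(10) within each decile
(raw fractions by flag), and defines the calibration slope as the
coefficient of the frozen linear predictor refit as the sole covariate —
the standard Cox calibration-slope definition, stated explicitly because
the term is used loosely in the literature.

Country-specific log hazard ratios (and C-statistics, on their own scale)
are pooled with DerSimonian–Laird random effects — the classical moment
estimator contemporaneous with the analyses this package supports — with
Q, τ² and I² reported; REML is deliberately not the default so that the
hand-computable DL formulas remain the reference.

## The synthetic cohort generator

The generator exists so that every downstream stage has testable ground
truth. It emulates the *structure* of a large pan-European cohort:

* 10 countries / 23 centers; 71.1% women; age ~ truncated normal
  (mean 50.8, SD 9.8, range 25–70).
* Covariate frequencies per sex (smoking 3-cat, education 4-cat,
  Cambridge physical-activity 4-cat, BMI normal) close to the published
  cohort characteristics table; the published activity frequencies leave
  a missing-category remainder and are renormalized over the four
  observed categories.
* Sixteen parent food groups drawn jointly log-normally. A latent
  standard-normal diet-quality factor `q` loads on the log intakes
  (positive for fruit, vegetables, legumes, nuts, fish; negative for
  meat, sweets, sugary drinks, margarine), and the configured
  correlation matrix is the **total** log-scale correlation, so
  `corr = λᵢλⱼ + residual`; the residual matrix must be positive
  definite. The fruit–vegetable default of 0.3 is therefore a
  conditional-on-sex, log-scale quantity — pooling sexes inflates raw
  Pearson correlations through the sex-specific energy shift, which is
  why validation measures it within sex.
* Sub-groups (whole-grain share of cereals, red/processed share of meat,
  low-fat share of dairy, fatty share of fish, …) are logit-normal
  shares, several loading on `q` so that whole-grain-sensitive scores
  pick up signal.
* Nutrients are the composition table times the food vector, with 10%
  multiplicative noise on micronutrients; macronutrients are exact, and
  energy is defined as the exact macronutrient energy, so energy
  consistency holds by construction. Sex-specific location shifts are
  solved in closed form so mean energy hits 2427.9 kcal/d (men) and
  1935.4 (women).
* Mortality uses the latent-failure-time construction: independent
  cause-specific Weibull hazards (CVD shape 4, cancer 3, other 2.5) with
  proportional effects of `q` (default per-SD HRs 0.85 / 0.90 / 0.87),
  age, sex, smoking and BMI, plus centered per-country offsets
  (SD 0.12). The observed cause is the earliest latent time;
  administrative censoring is a per-center horizon (11–14 years cycling
  across centers — calendar dates are not simulated). Baseline scales
  are solved numerically so the reference population's 10-year
  cumulative mortality is 3.4% (0.8% CVD / 1.7% cancer / 0.9% other):
  a per-cause closed-form solve, a fixed-point refinement under
  competing risks on a 101-point time grid (n = 10,000 reference
  draws), then a common rescaling matched on a 200,000-draw closed-form
  all-cause evaluation. The reference draws use fixed internal seeds, so
  defaults are deterministic, and results are cached per configuration.
* Prevalent-disease flags (cancer 4.46%, MI 1.34%, angina 1.60%, stroke
  0.80%, diabetes 2.65%) exist to be removed by the exclusion stage;
  breastfeeding and the obesity-related-cancer flag (38.4% of cancer
  deaths) are Bernoulli with configurable rates, as no distributions are
  published for them.

Reproducibility is block-wise: the master seed spawns one substream per
generation block (covariates, latent factor, intakes, flags, survival),
which keeps generation fully vectorized; per-subject streams were
considered and rejected as incompatible with vectorized drawing in R.
Two calls with the same configuration and seed are bit-identical.

What the generator does **not** emulate: questionnaire measurement error
and its calibration, calendar-time recruitment, within-center covariate
clustering, non-proportional hazards, and real food-composition
heterogeneity across countries. Passing tests therefore demonstrate the
*machinery* — scoring arithmetic, cut-off logic, model assembly,
estimator correctness — not that any particular published effect size
would replicate in real data.

## Validation design and problem sizes

The package's own validation (the test suite) uses: exhaustive
pair-enumeration oracles for Harrell's C at n ≤ 20; sort-based quantile
oracles; a hand Breslow computation at n = 6; a hand Kaplan–Meier
calibration table at n = 20; the hand DerSimonian–Laird example
(estimates 0 / 0.2 / 0.4, SEs 0.1 → Q = 8, τ² = 0.03, I² = 75%);
parameter recovery of a true per-SD HR of 0.85 over 50 replicates at
n = 100,000 (CI coverage ≥ 90%) and CI coverage within 93–97% over 400
replicates at n = 20,000 — 400 chosen so the binomial SE of the coverage
estimate (~1.1%) sits well inside the band; null-effect checks over 20
replicates; and self-calibration of a correctly specified model at
n = 200,000 (overall predicted-to-observed ratio and calibration slope
within ±0.03 of 1). The generator's event-fraction calibration is
checked at n = 100,000 against a ±0.003 band derived from the two
Monte-Carlo standard errors involved (reference draw and test draw).

## Known limitations

* Gram-based serving conversions (HEI cup/ounce equivalents, DQI-I and
  MSDPS servings) are single defaults, not food-item-resolved; they are
  deliberately exposed as configuration.
* The WCRF energy-density sub-component uses total dietary energy
  density over non-beverage food mass, a common operationalization but
  not the only one.
* Apparent (in-sample) discrimination and calibration are reported by
  design; optimism correction is out of scope.
* The obesity-related-cancer outcome is a synthetic flag, not an
  ICD-site classification.
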
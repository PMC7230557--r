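---
title: "Methods: severity scoring, synthetic cohorts and the tertile comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity scoring, synthetic cohorts and the tertile comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
the package: what each derived score computes, what the synthetic-cohort
generator emulates and deliberately does not, and the numerical decisions a
user adjusting the configuration should know about.

## The severity score and its configuration

The metabolic syndrome severity score treats the six harmonized components
— waist circumference (cm), triglycerides, HDL cholesterol, fasting glucose
(all mg/dL), systolic and diastolic blood pressure (mmHg) — as graded
exposures rather than binary criteria. Each component contributes its
standardized exceedance beyond the clinical threshold in the risk
direction, truncated at zero; HDL enters with a negative direction so that
low values contribute. The default aggregation is the plain sum; a
Euclidean (root-sum-of-squares) variant is available in
`metsss_config(aggregation = "euclidean")`.

Two properties pin the implementation down: the score is exactly zero when
every component sits at or below its threshold in the risk direction, and
it is non-decreasing in every risk-increasing component. The published
severity instrument this emulates is defined in a separate reference whose
exact coefficients are not restated here; the implementation therefore
exposes the thresholds (harmonized defaults: WC 102/88 cm men/women, TAG
150 mg/dL, HDL 40/50 mg/dL, BP 130/85 mmHg, glucose 100 mg/dL), the
per-component scales (reference within-component SDs) and the aggregation
as configuration, so a user holding the original coefficients can drop them
in. Medication use does not enter the severity score by default; it does
enter the binary component *flags* (drug-treated counts as meeting the
criterion) and the adjusted models' covariates.

Tertiles are empirical thirds of the score: inverse-ECDF quantiles
(`type = 1`), inclusive on the left (T1 ≤ q1/3 < T2 ≤ q2/3 < T3). This
tie-handling is deterministic and rank-based, so any strictly monotone
transform of the score yields identical groups. With all scores identical
the split is undefined and the function refuses rather than guessing.

## Derived indices

**VAI.** The sex-specific equations use reference lipid constants in
mmol/L; mg/dL inputs are converted (TAG ÷ 88.57, HDL ÷ 38.67) before
evaluation, otherwise the calibration VAI = 1 for the healthy reference
subject is unattainable. The reference identity — WC on the line
`39.68 + 1.88·BMI` (men) with TAG 1.03 and HDL 1.31 mmol/L — holds for any
BMI and is the package's central exactness check.

**DII.** Each food parameter's intake is standardized against a global
reference mean and SD, mapped to a centred percentile `2·Φ(z) − 1`, and
weighted by its signed inflammatory effect score. The percentile is the
standard-normal CDF of the z-score: the phrase "percentile score" admits
more than one reading, and the CDF reading is smooth, matches how a
z-score against a reference database is normally percentiled, and makes the
translation property testable (`adding k·sd moves the centred percentile by
2(Φ(z+k) − Φ(z))`). An empirical-percentile mode
(`compute_dii(..., percentile = "empirical")`) ranks against a supplied
cohort instead. The shipped parameter table covers the 30 parameters this
analysis uses (the full published framework has 45; a user-supplied table
of any size works). Its global means/SDs are *synthetic*: they are set at
the typical intake scale of the simulated population so the cohort's DII
centres near zero the way the real cohort's does. They are placeholders for
the proprietary global reference database, not estimates of it.

**MD-17.** The 17 food-habit criteria ship as an editable table of
predicates over daily food-group and nutrient intakes (variable, direction,
threshold). The instrument's exact items are not restated in the source
material this package follows, so the defaults are a declared convention
modelled on the energy-restricted Mediterranean screener family; analyses
caring about absolute adherence levels should substitute their instrument's
thresholds. The score is the count of met criteria, bounded 0–17 and
permutation-invariant over items.

**FFQ.** Nine frequency categories map to servings/day at their midpoints:
never = 0, 1–3/month = 2/30.4, 1/week = 1/7, 2–4/week = 3/7, 5–6/week =
5.5/7, 1/day = 1, 2–3/day = 2.5, 4–6/day = 5, ≥6/day = 6. All midpoints are
configurable. The printed convention `5–6/week → 0.78/day` is a *truncating*
two-decimal display of 0.7857…; truncation is applied only when formatting
(`format_servings()`), never in computation. Nutrient intakes are servings ×
per-portion composition summed over items, plus supplement micronutrients
for supplement users; %TE uses 4/4/9/7 kcal/g for carbohydrate, protein,
fat, alcohol; glycaemic index is the carbohydrate-weighted mean of per-item
values.

**Activity.** MET·min/week = MET × min/day × days/week. The printed
intensity classes (<4.0 light, 4–5.5 moderate, ≥6.0 vigorous) leave
(5.5, 6.0) unassigned; moderate is implemented as [4.0, 6.0) so the classes
partition all positive intensities while honouring both printed boundaries.
The total-PA outlier rule excludes subjects 3 or more SDs from their
stratum mean; "for each sex and age" is operationalized as sex × 5-year age
band (55–59, …, 70–75; configurable), because per-year strata would be
unstable at cohort scale. Stratum statistics are computed once on the data
entering that stage — a single pass, not an iterated trimming. The
12-category sitting-time instrument prints only its endpoints (0 to ≥9
h/day); the default mapping 0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9 is a
declared convention (half-hour steps to 2 h, hourly after, open-ended top
category at its lower bound) and is configurable. Sleep is the 5:2
weekday/weekend weighted mean.

## The synthetic cohort

The generator exists because the trial data are restricted. It emulates the
*study conditions*: men 55–75 y, women 60–75 y, BMI 27 to <40 kg/m², at
least three harmonized criteria (drug treatment counts), enforced by batch
rejection sampling with a cap of 1000 attempts per subject (infeasible
configurations fail with a diagnostic rather than looping).

One latent severity factor per subject drives everything coupled:

* the six metabolic components are correlated transforms of the factor
  plus residual noise (triglycerides log-normal, the rest normal, residual
  correlation matrix validated positive-definite with an eigenvalue
  diagnostic);
* medication probabilities are logistic in the factor;
* lifestyle variables receive configurable shifts by latent-severity
  tertile.

Component means/SDs and the factor loadings were fixed once against the
source analysis's printed baseline tables: locations at the overall table
means, and loadings sized so the waist-circumference and glucose gradients
across severity tertiles match the printed tertile means (about 1.1–1.3 SD
between extreme tertiles). With a single factor this necessarily makes the
blood-pressure and lipid gradients somewhat steeper than printed — a
one-knob construction cannot match six gradient magnitudes independently —
and component cross-correlations stronger than in free-living data. That
trade-off is deliberate: severity-score fidelity (and hence the behaviour
of tertile classification) takes priority over per-component marginal
fidelity, which is a declared non-goal beyond means, SDs and signs.

Lifestyle couplings are expressed in SD units of the target variable
between extreme latent tertiles, with two layouts: `"linear"` (default;
extremes at ± half the effect, matching the monotone gradients of the
printed tables) and `"top"` (the whole shift confined to the top tertile).
Default magnitudes follow the printed gradients: less moderate/vigorous
activity, more sedentary and TV time, higher depression scores, fewer
chair-stand repetitions, fewer nuts, more red/processed meat, non-olive
oils and spirits with increasing severity; sociodemographic tilts
(education, smoking, marital, employment) scale with a single
`sociodemographic` coupling so a null cohort is null *everywhere*
downstream tests look. LTPA shifts are applied multiplicatively to active
subjects' minutes so zero stays zero and the configured mean shift is exact
in expectation; an `ltpa_total` coupling distributes the shift over
intensity classes proportional to their overall means.

FFQ responses are generated by snapping a subject × food-group lognormal
intensity (with a common subject-level scale, including rare extreme
under-/over-reporters that feed the extreme-energy exclusion stage) to the
nearest of the nine category midpoints. Missingness rates for the
activity questionnaires, the FFQ and the risk-factor panel default to the
recruitment flow chart's proportions.

What the generator does **not** emulate: the real joint distribution beyond
the features above, follow-up visits, item-level FFQ validity or
measurement error, seasonality, or centre effects. Passing tests therefore
demonstrate that the *pipeline* is correct and calibrated — not that any
particular epidemiological estimate from real data would be reproduced.

## The exclusion cascade and the statistical layer

Exclusions run in the study's order — unanswered activity questionnaires,
total-PA outliers, extreme energy intake (outside 500–3500 kcal/day in
women, 800–4000 in men, boundaries inclusive), missing FFQ, incomplete
risk-factor information — and each subject is counted at its first failing
stage, so the flow report always conserves counts. The energy rule is
idempotent and order-independent with the other filters.

Group descriptives are mean ± sample SD and median (IQR), with quartiles by
the linear-interpolation convention (R `type = 7`); categoricals are n (%).
Comparisons across tertiles: Pearson chi-square without continuity
correction for categoricals; tie-corrected Kruskal–Wallis for non-normal
quantities; one-way ANOVA unadjusted; and ANCOVA read as a linear model
with the tertile factor (2 df test) plus additively entered, dummy-coded
covariates — sex and age, or the full set (education, smoking, marital,
employment, plus the five medication flags for the clinical table). With an
empty covariate set the ANCOVA p equals the ANOVA p exactly. Pairwise
tertile contrasts come from the same fitted model as coefficient
differences, with p-values multiplied by 3 and capped at 1; the table
renderer prints the pair letters (a: T1–T2, b: T1–T3, c: T2–T3) only when
the family test is itself significant. Normality is checked by a
Kolmogorov–Smirnov test against a normal with estimated mean and SD — i.e.
the Lilliefors correction, since the reference parameters are not
prespecified — and variance homogeneity by Levene's test on absolute
deviations from group means. Missing data are handled complete-case per
variable, with per-group n reported.

## Calibration studies and problem sizes

Two simulation studies validate the statistical layer end to end. Under the
null (all couplings zero) the ANOVA, ANCOVA, Kruskal–Wallis and chi-square
comparisons across severity tertiles are checked to reject at the nominal
5% rate, within [0.03, 0.07] over 1000 replicate cohorts of n = 600 — sizes
chosen to make a two-sided binomial check of the rate sharp while keeping
the study quick to re-run. Effect recovery configures a 0.25 SD total-LTPA
deficit in the top latent-severity tertile at n = 3000 and requires the
fully adjusted comparison to flag it in at least 90% of 100 replicates.
`analysis/04_calibration.R` reruns reduced versions (200 and 50
replicates) as a fast demonstration; the full versions live in the test
suite. Tertile cut-point consistency is checked on 10⁵ draws from a known
normal distribution against its analytic tertiles at 1% relative
tolerance.

## Known limitations

* The severity score is a contract-faithful stand-in for the published
  instrument, not a re-derivation of its coefficients; absolute tertile
  cut-points from synthetic data should not be compared against published
  cut-points.
* The food-composition matrix and the DII reference table are synthetic
  and calibrated only at the cohort-mean level; item-level nutrient values
  are not meaningful individually.
* FFQ category quantization biases very-low-frequency items toward
  "never"; group totals absorb this, single-item analyses would not.
* Pairwise letters derive from covariate-adjusted model contrasts; an
  analysis wanting unadjusted pairwise tests can read them off
  `test_quantitative(..., covariates = character(0))`.
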
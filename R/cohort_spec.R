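#' Specification of a synthetic cohort
#'
#' Defines the study conditions the generator emulates: an older Spanish
#' population with overweight/obesity (BMI 27 to <40 kg/m^2), sex-specific
#' age windows (men 55-75, women 60-75), at least three harmonized metabolic
#' syndrome criteria, correlated metabolic components driven by a single
#' latent severity factor, severity-dependent medication use, and optional
#' couplings from severity to lifestyle variables. Default locations, spreads
#' and coupling magnitudes are sized to the gradients the source cohort's
#' baseline tables print; they are package choices, not estimates of the
#' restricted data.
#'
#' @param n_subjects Number of subjects to generate (>= 0).
#' @param fraction_women Proportion of women in (0, 1); the generated count
#'   is `round(fraction_women * n_subjects)`.
#' @param seed Integer seed; identical spec + seed gives an identical cohort.
#' @param age_range_men,age_range_women Eligible age windows, years.
#' @param bmi_range Eligible BMI window `[lo, hi)`, kg/m^2.
#' @param component_means_male,component_means_female Pre-selection location
#'   of the six metabolic components (`wc` cm, `tag` mg/dL on the natural
#'   scale, `hdl` mg/dL, `sbp`/`dbp` mmHg, `glucose` mg/dL).
#' @param component_sds Pre-selection spread per component (for `tag` the
#'   log-scale SD).
#' @param component_loadings Loading of each component on the latent severity
#'   factor, in (0, 1); the signed loading for HDL is negative internally.
#' @param component_correlation 6 x 6 residual correlation matrix
#'   (symmetric positive-definite) over the components, order
#'   wc, tag, hdl, sbp, dbp, glucose.
#' @param effect_shape How lifestyle shifts are laid out over latent
#'   severity tertiles: `"linear"` (default) places the extremes at +/- half
#'   the configured effect so T3 - T1 equals it, matching the monotone
#'   gradients of the source tables; `"top"` confines the whole shift to the
#'   top tertile (T1 = T2 = 0, T3 = effect).
#' @param effect_sizes Named numeric couplings from latent severity to
#'   lifestyle variables. Continuous variables (`ltpa_total`, `ltpa_light`,
#'   `ltpa_moderate`, `ltpa_vigorous`, `sedentary`, `tv`, `bdi`,
#'   `chair_stand`, `sleep`) are mean differences between the extreme latent
#'   severity tertiles in SD units of the variable. Food groups (`nuts`,
#'   `red_meat`, `processed_meat`, `other_oils`, `spirits`) are log
#'   consumption-intensity differences between extreme tertiles. Set all to
#'   zero for a null cohort.
#' @param medication_logit Named list of `c(intercept, slope)` pairs for the
#'   logistic dependence of each drug class on latent severity.
#' @param missing_rates Named rates in `[0, 1]` for `pa` (physical-activity
#'   questionnaires not answered), `ffq` (no FFQ) and `risk_info` (a missing
#'   metabolic component), matching the recruitment flow chart's proportions.
#' @param max_attempts_per_subject Rejection-sampling cap for the eligibility
#'   constraints.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_subjects,
    fraction_women = 0.477,
    seed = 1L,
    age_range_men = c(55, 75),
    age_range_women = c(60, 75),
    bmi_range = c(27, 40),
    component_means_male = c(wc = 106, tag = 135, hdl = 46, sbp = 137,
                             dbp = 81, glucose = 106),
    component_means_female = c(wc = 96, tag = 135, hdl = 53, sbp = 137,
                               dbp = 81, glucose = 106),
    component_sds = c(wc = 9, tag = 0.35, hdl = 11, sbp = 16, dbp = 10,
                      glucose = 22),
    component_loadings = c(wc = 0.85, tag = 0.70, hdl = 0.50, sbp = 0.70,
                           dbp = 0.60, glucose = 0.80),
    component_correlation = default_component_correlation(),
    effect_sizes = default_effect_sizes(),
    effect_shape = c("linear", "top"),
    medication_logit = list(
      antihypertensive = c(1.25, 0.15),
      cholesterol = c(0.05, 0.10),
      insulin = c(-3.60, 0.95),
      oral_hypoglycaemic = c(-1.35, 0.80),
      aspirin = c(-1.85, 0.35)
    ),
    missing_rates = c(pa = 0.034, ffq = 0.006, risk_info = 0.081),
    max_attempts_per_subject = 1000) {
  comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
  if (n_subjects < 0 || n_subjects != floor(n_subjects)) {
    stop("n_subjects must be a non-negative integer", call. = FALSE)
  }
  if (fraction_women < 0 || fraction_women > 1) {
    stop("fraction_women must be in [0, 1]", call. = FALSE)
  }
  for (v in list(component_means_male, component_means_female, component_sds,
                 component_loadings)) {
    if (!setequal(names(v), comp)) {
      stop("component parameters must name: ", paste(comp, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(component_sds <= 0)) stop("component SDs must be positive", call. = FALSE)
  if (any(component_loadings <= 0 | component_loadings >= 1)) {
    stop("component loadings must lie in (0, 1)", call. = FALSE)
  }
  R <- as.matrix(component_correlation)
  if (!isTRUE(all.equal(R, t(R))) || any(diag(R) != 1)) {
    stop("component_correlation must be a symmetric correlation matrix",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("component_correlation is not positive-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  }
  effect_shape <- match.arg(effect_shape)
  effects <- default_effect_sizes()
  effects[names(effect_sizes)] <- effect_sizes
  rates <- c(pa = 0, ffq = 0, risk_info = 0)
  rates[names(missing_rates)] <- missing_rates
  if (any(rates < 0 | rates > 1)) {
    stop("missing rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    fraction_women = fraction_women,
    seed = as.integer(seed),
    age_range_men = age_range_men,
    age_range_women = age_range_women,
    bmi_range = bmi_range,
    component_means_male = component_means_male[comp],
    component_means_female = component_means_female[comp],
    component_sds = component_sds[comp],
    component_loadings = component_loadings[comp],
    component_correlation = R,
    effect_sizes = effects,
    effect_shape = effect_shape,
    medication_logit = medication_logit,
    missing_rates = rates,
    max_attempts_per_subject = max_attempts_per_subject
  ), class = "cohort_spec")
}

#' Default residual correlation over the six metabolic components
#'
#' Mild positive residual dependence among pressure and adiposity/lipid
#' components beyond the shared severity factor; the source tables do not
#' report component correlations, so these are package defaults.
#'
#' @return 6 x 6 correlation matrix (wc, tag, hdl, sbp, dbp, glucose).
#' @export
default_component_correlation <- function() {
  comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
  R <- diag(6)
  dimnames(R) <- list(comp, comp)
  R["wc", "tag"] <- R["tag", "wc"] <- 0.15
  R["wc", "hdl"] <- R["hdl", "wc"] <- -0.10
  R["tag", "hdl"] <- R["hdl", "tag"] <- -0.30
  R["sbp", "dbp"] <- R["dbp", "sbp"] <- 0.55
  R["wc", "glucose"] <- R["glucose", "wc"] <- 0.10
  R["tag", "glucose"] <- R["glucose", "tag"] <- 0.10
  R
}

#' Default severity-lifestyle couplings
#'
#' Signs and magnitudes follow the gradients printed in the source cohort's
#' baseline tables: less moderate/vigorous activity, more sedentary and TV
#' time, more depressive symptoms, fewer chair-stand repetitions, fewer nuts
#' and more red/processed meat, non-olive oils and spirits with increasing
#' severity.
#'
#' @return Named numeric vector of couplings (see [cohort_spec()]).
#' @export
default_effect_sizes <- function() {
  c(ltpa_total = 0, ltpa_light = 0, ltpa_moderate = -0.20,
    ltpa_vigorous = -0.17,
    sedentary = 0.15, tv = 0.15, sleep = 0, bdi = 0.27, chair_stand = -0.32,
    nuts = -0.16, red_meat = 0.06, processed_meat = 0.07, other_oils = 0.19,
    spirits = 0.08, sociodemographic = 1)
}

#' A null version of a cohort specification
#'
#' Returns the spec with every severity-lifestyle coupling set to zero and
#' (by default) no missingness, for calibration studies.
#'
#' @param spec A `cohort_spec`.
#' @param missing Keep the missingness rates? Default drops them.
#' @return Modified `cohort_spec`.
#' @export
null_spec <- function(spec, missing = FALSE) {
  spec$effect_sizes[] <- 0
  if (!missing) spec$missing_rates[] <- 0
  spec
}
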
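# Synthetic cohort generation: one latent severity factor per subject drives
# correlated metabolic components, medication probabilities and (when coupled)
# lifestyle variables. Eligibility (sex-specific age window, BMI 27 to <40,
# >= 3 harmonized MetS criteria) is enforced by batch rejection sampling.

#' Generate a synthetic cohort
#'
#' Draws eligible subjects under the study conditions in `spec`, plus
#' companion long-format tables: leisure-time activity records, sedentary and
#' sleep responses, Beck Depression Inventory-II items and (optionally) the
#' 143-item FFQ. All randomness flows from `spec$seed`; identical spec gives
#' a byte-identical cohort. The latent severity factor and its tertile are
#' retained in the subject table (columns `latent_severity`,
#' `latent_tertile`) as simulation ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param include_ffq Generate the FFQ layer (slowest part); set `FALSE` for
#'   calibration studies that do not touch diet.
#' @return Object of class `metsev_cohort`: list with `subjects`, `activity`,
#'   `sedentary`, `bdi`, `ffq` (or `NULL`) and the `spec`.
#' @export
generate_cohort <- function(spec, include_ffq = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  if (n == 0) {
    return(empty_cohort(spec))
  }
  n_w <- round(spec$fraction_women * n)
  n_m <- n - n_w
  males <- draw_eligible_subjects(spec, "male", n_m)
  females <- draw_eligible_subjects(spec, "female", n_w)
  subjects <- rbind(males, females)
  subjects <- subjects[sample.int(nrow(subjects)), , drop = FALSE]
  subjects$subject_id <- seq_len(nrow(subjects))
  rownames(subjects) <- NULL

  # latent severity tertile used for lifestyle couplings
  if (n >= 3 && length(unique(subjects$latent_severity)) > 1) {
    subjects$latent_tertile <- assign_tertiles(subjects$latent_severity)$tertile
  } else {
    subjects$latent_tertile <- factor(rep("T2", n), levels = c("T1", "T2", "T3"))
  }
  g <- as.integer(subjects$latent_tertile)

  # anthropometry beyond BMI, derived biochemistry
  subjects$height <- round(ifelse(subjects$sex == "male",
                                  stats::rnorm(n, 1.70, 0.06),
                                  stats::rnorm(n, 1.58, 0.055)), 2)
  subjects$weight <- round(subjects$bmi * subjects$height^2, 1)
  subjects$hr <- round(stats::rnorm(n, 69, 9.5) +
                         2.3 * subjects$latent_severity, 1)
  subjects$hba1c <- round(3.75 + 0.020 * subjects$glucose +
                            stats::rnorm(n, 0, 0.28), 1)
  ldl_core <- stats::rnorm(n, 122, 40)
  subjects$tc <- round(ldl_core + subjects$hdl + subjects$tag / 5, 0)

  # sociodemographics: multinomial with mild severity-dependent tilts,
  # scaled by the sociodemographic coupling (0 = independent of severity)
  socio <- spec$effect_sizes[["sociodemographic"]]
  subjects$education <- draw_tilted(c(illiterate_primary = 0.49,
                                      secondary = 0.29,
                                      academic = 0.22),
                                    tilt = socio * c(0.10, 0, -0.12),
                                    subjects$latent_severity)
  subjects$smoking <- draw_tilted(c(never = 0.44, former = 0.43,
                                    current = 0.13),
                                  tilt = socio * c(0.10, -0.08, -0.04),
                                  subjects$latent_severity)
  subjects$marital <- draw_tilted(c(single_divorced = 0.13, married = 0.76,
                                    widowed = 0.11),
                                  tilt = socio * c(0.02, -0.06, 0.10),
                                  subjects$latent_severity)
  subjects$employment <- draw_tilted(c(working = 0.20, non_working = 0.23,
                                       retired = 0.57),
                                     tilt = socio * c(-0.06, 0.12, -0.03),
                                     subjects$latent_severity)

  # lifestyle layers
  eff <- spec$effect_sizes
  shp <- tertile_shape(g, spec$effect_shape)
  activity <- draw_activity(subjects, eff, shp)
  ltpa <- summarize_ltpa(activity, subjects$subject_id)
  subjects <- merge(subjects, ltpa, by = "subject_id", sort = FALSE)
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]

  sedentary <- draw_sedentary(subjects, eff, shp)
  bdi <- draw_bdi(subjects, eff, shp)
  subjects$bdi_score <- bdi_total(bdi[, -1])

  shift_cs <- eff["chair_stand"] * shp
  subjects$chair_stand <- pmax(0, round(stats::rnorm(n, 13.3, 5.0) +
                                          5.0 * shift_cs))
  subjects$supplement_user <- stats::runif(n) < 0.15

  # missingness emulating the recruitment flow chart
  subjects$pa_missing <- stats::runif(n) < spec$missing_rates["pa"]
  subjects$ffq_missing <- stats::runif(n) < spec$missing_rates["ffq"]
  miss_risk <- which(stats::runif(n) < spec$missing_rates["risk_info"])
  if (length(miss_risk) > 0) {
    comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
    which_comp <- sample(comp, length(miss_risk), replace = TRUE)
    for (i in seq_along(miss_risk)) {
      subjects[miss_risk[i], which_comp[i]] <- NA_real_
    }
  }
  subjects$ltpa_light[subjects$pa_missing] <- NA_real_
  subjects$ltpa_moderate[subjects$pa_missing] <- NA_real_
  subjects$ltpa_vigorous[subjects$pa_missing] <- NA_real_
  subjects$ltpa_total[subjects$pa_missing] <- NA_real_
  subjects$ltpa_weekly_total[subjects$pa_missing] <- NA_real_

  ffq <- NULL
  if (include_ffq) {
    ffq <- generate_ffq_responses(subjects, spec)
  }
  structure(list(subjects = subjects, activity = activity,
                 sedentary = sedentary, bdi = bdi, ffq = ffq, spec = spec),
            class = "metsev_cohort")
}

# per-tertile layout of a configured lifestyle shift
tertile_shape <- function(g, shape) {
  if (shape == "top") as.numeric(g == 3L) else (g - 2) / 2
}

empty_cohort <- function(spec) {
  structure(list(
    subjects = data.frame(subject_id = integer(0)),
    activity = data.frame(subject_id = integer(0), activity = character(0),
                          met_score = numeric(0), minutes_per_day = numeric(0),
                          days_per_week = integer(0)),
    sedentary = data.frame(subject_id = integer(0)),
    bdi = data.frame(subject_id = integer(0)),
    ffq = data.frame(subject_id = integer(0), item_id = integer(0),
                     category = character(0)),
    spec = spec
  ), class = "metsev_cohort")
}

#' @export
print.metsev_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects",
      sprintf("(%.1f%% women), seed %d\n",
              100 * mean(x$subjects$sex == "female"), x$spec$seed))
  if (!is.null(x$ffq)) cat("FFQ responses:", nrow(x$ffq), "rows\n")
  invisible(x)
}

# --- internal draws ---------------------------------------------------------

# batch rejection sampling of eligible subjects of one sex
draw_eligible_subjects <- function(spec, sex, n_target) {
  if (n_target == 0) {
    out <- draw_candidates(spec, sex, 1)[0, , drop = FALSE]
    return(out)
  }
  comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
  kept <- NULL
  attempts <- 0
  cap <- spec$max_attempts_per_subject * n_target
  while (is.null(kept) || nrow(kept) < n_target) {
    need <- n_target - if (is.null(kept)) 0 else nrow(kept)
    m <- max(200, ceiling(2.5 * need))
    if (attempts + m > cap) m <- cap - attempts
    if (m <= 0) {
      stop("eligibility constraints unreachable: exceeded ",
           spec$max_attempts_per_subject, " attempts per subject (",
           if (is.null(kept)) 0 else nrow(kept), "/", n_target,
           " accepted). Check thresholds against component ranges.",
           call. = FALSE)
    }
    cand <- draw_candidates(spec, sex, m)
    attempts <- attempts + m
    ok_bmi <- cand$bmi >= spec$bmi_range[1] & cand$bmi < spec$bmi_range[2]
    flags <- mets_component_flags(cand)
    ok <- ok_bmi & flags$n_mets_criteria >= 3
    kept <- rbind(kept, cand[ok, , drop = FALSE])
  }
  kept[seq_len(n_target), , drop = FALSE]
}

# raw candidate draws before eligibility filtering
draw_candidates <- function(spec, sex, m) {
  comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
  rng <- if (sex == "male") spec$age_range_men else spec$age_range_women
  mu <- if (sex == "male") spec$component_means_male else
    spec$component_means_female
  z <- stats::rnorm(m)
  bmi <- 32.2 + 3.3 * (0.55 * z + sqrt(1 - 0.55^2) * stats::rnorm(m))
  eps <- matrix(stats::rnorm(m * 6), m, 6) %*%
    chol(spec$component_correlation)
  w <- spec$component_loadings
  sgn <- c(wc = 1, tag = 1, hdl = -1, sbp = 1, dbp = 1, glucose = 1)
  x <- matrix(NA_real_, m, 6, dimnames = list(NULL, comp))
  for (j in seq_along(comp)) {
    cj <- comp[j]
    core <- sgn[cj] * w[cj] * z + sqrt(1 - w[cj]^2) * eps[, j]
    if (cj == "tag") {
      x[, j] <- exp(log(mu[cj]) + spec$component_sds[cj] * core)
    } else {
      x[, j] <- mu[cj] + spec$component_sds[cj] * core
    }
  }
  d <- data.frame(sex = sex, age = round(stats::runif(m, rng[1], rng[2]), 1),
                  latent_severity = z, bmi = round(bmi, 1))
  d <- cbind(d, round(as.data.frame(x), 1))
  d$hdl <- pmax(d$hdl, 15)
  d$glucose <- pmax(d$glucose, 55)
  for (drug in names(spec$medication_logit)) {
    ab <- spec$medication_logit[[drug]]
    d[[paste0("med_", drug)]] <-
      stats::runif(m) < stats::plogis(ab[1] + ab[2] * z)
  }
  d
}

# multinomial category draw with a log-linear tilt in latent severity
draw_tilted <- function(base_p, tilt, z) {
  lp <- outer(z, tilt) + matrix(log(base_p), length(z), length(base_p),
                                byrow = TRUE)
  p <- exp(lp)
  p <- p / rowSums(p)
  u <- stats::runif(length(z))
  cum <- t(apply(p, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  factor(names(base_p)[idx], levels = names(base_p))
}

# leisure-time activity records: zero-inflated gamma weekly MET-min per
# intensity class, converted to one compendium-coded record per active class
ltpa_class_params <- function() {
  list(
    light = list(p = 0.80, mu = 963, shape = 0.9,
                 acts = c(walking = 3.3, gardening_light = 3.0,
                          home_exercises = 3.5)),
    moderate = list(p = 0.70, mu = 1280, shape = 0.8,
                    acts = c(brisk_walking = 4.5, cycling_easy = 5.5,
                             dancing = 4.5, gardening_heavy = 4.0)),
    vigorous = list(p = 0.55, mu = 1236, shape = 0.7,
                    acts = c(running = 8.0, swimming = 7.0,
                             cycling_fast = 6.0))
  )
}

draw_activity <- function(subjects, eff, shp) {
  n <- nrow(subjects)
  params <- ltpa_class_params()
  # an ltpa_total coupling moves total daily MET-min by the configured SD
  # fraction, distributed over classes proportional to their overall means
  cls_var <- vapply(params, function(pp) {
    (pp$p * pp$mu^2 * (1 + 1 / pp$shape) - (pp$p * pp$mu)^2) / 49
  }, numeric(1))
  cls_mean <- vapply(params, function(pp) pp$p * pp$mu / 7, numeric(1))
  sd_total <- sqrt(sum(cls_var))
  e_tot <- if ("ltpa_total" %in% names(eff)) eff[["ltpa_total"]] else 0
  recs <- list()
  for (cls in names(params)) {
    pp <- params[[cls]]
    # analytic SD of the zero-inflated daily value, for effect-size units
    sd_daily <- sqrt(cls_var[[cls]])
    e <- eff[paste0("ltpa_", cls)]
    shift_daily <- (e * sd_daily +
      e_tot * sd_total * (cls_mean[[cls]] / sum(cls_mean))) * shp
    fac <- pmax(0.05, 1 + shift_daily * 7 / (pp$p * pp$mu))
    active <- stats::runif(n) < pp$p
    weekly <- stats::rgamma(n, shape = pp$shape,
                            rate = pp$shape / pp$mu) * fac
    idx <- which(active & weekly > 0)
    if (length(idx) == 0) next
    act <- sample(names(pp$acts), length(idx), replace = TRUE)
    met <- unname(pp$acts[act])
    days <- sample(1:7, length(idx), replace = TRUE,
                   prob = c(1, 2, 3, 3, 3, 2, 2))
    minutes <- round(weekly[idx] / (met * days), 1)
    recs[[cls]] <- data.frame(subject_id = subjects$subject_id[idx],
                              activity = act, met_score = met,
                              minutes_per_day = minutes,
                              days_per_week = days,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(subject_id = integer(0), activity = character(0),
                      met_score = numeric(0), minutes_per_day = numeric(0),
                      days_per_week = integer(0))
  }
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sedentary behaviour categories, sleep hours
draw_sedentary <- function(subjects, eff, shp) {
  n <- nrow(subjects)
  v <- sedentary_category_hours()
  cuts <- utils::head(v, -1) + diff(v) / 2
  to_cat <- function(hours) pmin(12L, findInterval(hours, cuts) + 1L)
  sed_latent <- stats::rnorm(n, 8.0, 1.9) + eff["sedentary"] * 1.9 * shp
  tv_latent <- stats::rnorm(n, 5.1, 1.8) + eff["tv"] * 1.8 * shp
  pc_latent <- pmax(0, stats::rnorm(n, 0.9, 1.1))
  jr_latent <- pmax(0, stats::rnorm(n, 0.9, 0.8))
  sleep_wd <- pmax(3, round(stats::rnorm(n, 7.0, 1.2) +
                              eff["sleep"] * 1.2 * shp, 1))
  data.frame(
    subject_id = subjects$subject_id,
    cat_tv = to_cat(tv_latent),
    cat_computer = to_cat(pc_latent),
    cat_journeys = to_cat(jr_latent),
    cat_total_sitting = to_cat(pmax(sed_latent, tv_latent)),
    sleep_weekday = sleep_wd,
    sleep_weekend = pmax(3, round(sleep_wd + stats::rnorm(n, 0.25, 0.5), 1))
  )
}

# BDI-II items via a graded-threshold model on a depression latent
draw_bdi <- function(subjects, eff, shp) {
  n <- nrow(subjects)
  d <- stats::rnorm(n) + eff["bdi"] * shp
  jit <- seq(-0.3, 0.3, length.out = 21)
  items <- matrix(0L, n, 21)
  for (j in 1:21) {
    x <- d + stats::rlogis(n, 0, 0.6)
    items[, j] <- (x > 0.9 + jit[j]) + (x > 2.0 + jit[j]) +
      (x > 3.0 + jit[j])
  }
  out <- data.frame(subject_id = subjects$subject_id, items)
  names(out)[-1] <- paste0("bdi_", 1:21)
  out
}

#' Generate FFQ responses for a cohort's subjects
#'
#' Each subject receives exactly one frequency category per FFQ item. A
#' subject-level intake scale (with occasional extreme under-/over-reporters,
#' emulating the extreme-energy tail the exclusion cascade removes) and
#' per-food-group lognormal intensities set a target daily amount per item,
#' which is snapped to the nearest of the nine category midpoints. Food
#' groups named in the spec's effect sizes (nuts, red/processed meat,
#' non-olive oils, spirits) have their intensity tilted by latent severity
#' tertile.
#'
#' @param subjects Subject data frame from [generate_cohort()] (needs
#'   `subject_id`, `latent_tertile`, `ffq_missing`).
#' @param spec The [cohort_spec()].
#' @param fct Food-composition table (for portions and group membership).
#' @return Long data frame: `subject_id`, `item_id`, `category`.
#' @export
generate_ffq_responses <- function(subjects, spec,
                                   fct = default_food_composition()) {
  n <- nrow(subjects)
  if (n == 0) {
    return(data.frame(subject_id = integer(0), item_id = integer(0),
                      category = character(0)))
  }
  shp <- tertile_shape(as.integer(subjects$latent_tertile),
                       if (is.null(spec$effect_shape)) "linear" else
                         spec$effect_shape)
  groups <- unique(fct$food_group)
  daily_g <- default_group_daily_g()

  scale_subj <- exp(stats::rnorm(n, 0, 0.18) - 0.18^2 / 2)
  u <- stats::runif(n)
  scale_subj[u < 0.013] <- scale_subj[u < 0.013] *
    stats::runif(sum(u < 0.013), 1.7, 2.4)
  hi <- u >= 0.013 & u < 0.026
  scale_subj[hi] <- scale_subj[hi] * stats::runif(sum(hi), 0.15, 0.35)

  eff <- spec$effect_sizes
  coupled <- intersect(names(eff), groups)

  mids <- ffq_frequency_levels()
  cuts <- utils::head(mids, -1) + diff(mids) / 2

  resp <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    grp <- groups[k]
    items <- fct[fct$food_group == grp, , drop = FALSE]
    ni <- nrow(items)
    tilt <- if (grp %in% coupled) exp(eff[grp] * shp) else 1
    intensity <- daily_g[grp] * scale_subj * tilt *
      exp(stats::rnorm(n, 0, 0.40) - 0.40^2 / 2)
    # equal grams share per item within the group
    grams <- outer(intensity / ni, rep(1, ni))
    servings <- sweep(grams, 2, items$portion_g, "/")
    cat_idx <- findInterval(servings, cuts) + 1L
    resp[[k]] <- data.frame(
      subject_id = rep(subjects$subject_id, ni),
      item_id = rep(items$item_id, each = n),
      category = names(mids)[cat_idx]
    )
  }
  out <- do.call(rbind, resp)
  out <- out[!(out$subject_id %in% subjects$subject_id[subjects$ffq_missing %in% TRUE]), ]
  out <- out[order(out$subject_id, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
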
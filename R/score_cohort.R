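#' Score a cohort: nutrition, diet quality, activity and risk indices
#'
#' Computes every derived measure the tertile comparison needs, appending
#' columns to the subject table: total energy and the nutrient intakes of
#' interest (FFQ x composition matrix, plus supplement micronutrients for
#' supplement users), %TE macronutrients, intake-weighted glycaemic index,
#' daily food-group grams, the dietary inflammatory index, 17-item
#' Mediterranean diet adherence, sedentary/TV/sleep hours, Friedewald LDL,
#' visceral adiposity index, and the metabolic syndrome severity score.
#' Missing inputs propagate to missing scores; nothing is imputed.
#'
#' @param cohort A `metsev_cohort` (or a compatible list of tables).
#' @param fct Food-composition table.
#' @param dii_params DII parameter table.
#' @param md17 MD adherence criteria table.
#' @param metsss_cfg A [metsss_config()].
#' @param supplement Named numeric vector of daily micronutrient intakes
#'   added for supplement users.
#' @return The subject data frame with score columns appended.
#' @export
score_cohort <- function(cohort,
                         fct = default_food_composition(),
                         dii_params = dii_parameters_default(),
                         md17 = md17_criteria_default(),
                         metsss_cfg = metsss_config(),
                         supplement = default_supplement()) {
  subjects <- cohort$subjects
  n <- nrow(subjects)
  if (n == 0) return(subjects)

  # nutrient intakes: servings matrix (n x items) %*% per-portion contents
  nut_cols <- fct_nutrient_columns(fct)
  prof <- matrix(NA_real_, n, length(nut_cols),
                 dimnames = list(NULL, nut_cols))
  gi <- rep(NA_real_, n)
  fg <- matrix(NA_real_, n, length(unique(fct$food_group)),
               dimnames = list(NULL, unique(fct$food_group)))
  if (!is.null(cohort$ffq) && nrow(cohort$ffq) > 0) {
    ffq <- cohort$ffq
    row <- match(ffq$subject_id, subjects$subject_id)
    col <- match(ffq$item_id, fct$item_id)
    serv <- matrix(0, n, nrow(fct))
    serv[cbind(row, col)] <- frequency_to_per_day(ffq$category)
    has_ffq <- subjects$subject_id %in% unique(ffq$subject_id)
    nut_mat <- as.matrix(fct[nut_cols])
    prof[has_ffq, ] <- (serv %*% nut_mat)[has_ffq, ]
    carb_items <- serv * matrix(fct$carbohydrate_g, n, nrow(fct), byrow = TRUE)
    carb_tot <- rowSums(carb_items)
    gi_num <- as.vector(carb_items %*% fct$gi)
    gi[has_ffq] <- ifelse(carb_tot[has_ffq] > 0,
                          gi_num[has_ffq] / carb_tot[has_ffq], 0)
    grams <- serv * matrix(fct$portion_g, n, nrow(fct), byrow = TRUE)
    group_ind <- outer(fct$food_group, colnames(fg), "==") * 1
    fg[has_ffq, ] <- (grams %*% group_ind)[has_ffq, ]
  }

  # supplements contribute micronutrients for users
  if ("supplement_user" %in% names(subjects) && !is.null(supplement)) {
    users <- subjects$supplement_user %in% TRUE
    for (nm in names(supplement)) {
      prof[users, nm] <- prof[users, nm] + supplement[[nm]]
    }
  }

  out <- cbind(subjects, as.data.frame(prof), gi = gi, as.data.frame(fg))
  # aggregate food groups reported as totals
  out$fish_seafood <- out$white_fish + out$bluefish + out$seafood
  out$total_meat <- out$red_meat + out$white_meat + out$processed_meat +
    out$viscera
  out$dairy <- out$whole_dairy + out$skimmed_dairy + out$cheese +
    out$dairy_desserts
  out$cereals <- out$whole_cereals + out$refined_cereals
  e <- out$energy_kcal
  out$carbohydrate_pte <- ifelse(e > 0, 100 * out$carbohydrate_g * 4 / e, 0)
  out$protein_pte <- ifelse(e > 0, 100 * out$protein_g * 4 / e, 0)
  out$fat_pte <- ifelse(e > 0, 100 * out$fat_g * 9 / e, 0)
  out$mufa_pte <- ifelse(e > 0, 100 * out$mufa_g * 9 / e, 0)
  out$pufa_pte <- ifelse(e > 0, 100 * out$pufa_g * 9 / e, 0)
  out$sfa_pte <- ifelse(e > 0, 100 * out$sfa_g * 9 / e, 0)

  # dietary inflammatory index, vectorized over subjects
  vars <- dii_params$intake_variable
  intake_mat <- as.matrix(out[vars])
  zc <- sweep(sweep(intake_mat, 2, dii_params$global_mean), 2,
              dii_params$global_sd, "/")
  out$dii <- as.vector((2 * stats::pnorm(zc) - 1) %*% dii_params$effect_score)

  # 17-item Mediterranean diet adherence, vectorized
  md_vals <- as.matrix(out[md17$variable])
  met <- matrix(NA, n, 17)
  for (j in 1:17) {
    met[, j] <- if (md17$op[j] == ">=") md_vals[, j] >= md17$threshold[j]
    else md_vals[, j] <= md17$threshold[j]
  }
  out$md17 <- as.integer(rowSums(met))

  # sedentary behaviour and sleep
  if (!is.null(cohort$sedentary) && nrow(cohort$sedentary) > 0) {
    sed <- cohort$sedentary[match(out$subject_id,
                                  cohort$sedentary$subject_id), ]
    out$sedentary_h <- sedentary_hours(sed$cat_total_sitting)
    out$tv_h <- sedentary_hours(sed$cat_tv)
    out$sleep_h <- sleep_average(sed$sleep_weekday, sed$sleep_weekend)
  }

  # clinical indices
  out$ldl <- friedewald_ldl(out$tc, out$hdl, out$tag)
  out$vai <- compute_vai(out$sex, out$wc, out$bmi, out$tag, out$hdl)
  out$metsss <- compute_metsss(out, metsss_cfg)
  mets_flags <- mets_component_flags(out, metsss_cfg)
  cbind(out, mets_flags)
}

#' Default daily micronutrient supplement
#'
#' A typical multivitamin/mineral contribution added to food intakes for
#' supplement users.
#'
#' @return Named numeric vector in the nutrient-profile vocabulary.
#' @export
default_supplement <- function() {
  c(vitamin_b9_ug = 200, vitamin_b12_ug = 2.5, vitamin_c_mg = 60,
    vitamin_d_ug = 5, vitamin_e_mg = 10, iron_mg = 5, zinc_mg = 5,
    iodine_ug = 75)
}

#' Run the exclusion cascade and assign severity tertiles
#'
#' Applies the five-stage study cascade to a scored cohort, then stratifies
#' the analysed subjects into metabolic syndrome severity tertiles.
#'
#' @param scored Scored subject table from [score_cohort()].
#' @param stages Stage predicates, default [default_exclusion_stages()].
#' @return List: `analysed` (subject table with `tertile` column), `flow`,
#'   `cutpoints`, `n_initial`, `n_final`.
#' @export
analyse_cohort <- function(scored, stages = default_exclusion_stages()) {
  res <- apply_exclusions(scored, stages)
  tert <- assign_tertiles(res$subjects$metsss)
  res$subjects$tertile <- tert$tertile
  list(analysed = res$subjects, flow = res$flow, cutpoints = tert$cutpoints,
       n_initial = res$n_initial, n_final = res$n_final)
}
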
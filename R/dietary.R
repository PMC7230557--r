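#' Frequency vocabulary of the 143-item food-frequency questionnaire
#'
#' The semi-quantitative FFQ records consumption of each item in nine ordered
#' categories, from "never or almost never" to six or more times per day.
#' Categories are converted to servings/day at their midpoints; weekly
#' midpoints are divided by 7, the monthly midpoint by the average month
#' length (30.4 days).
#'
#' @param midpoints Optional named numeric vector overriding the default
#'   servings/day midpoint for each of the nine categories.
#' @return Named numeric vector of length 9: servings/day per category label.
#' @export
ffq_frequency_levels <- function(midpoints = NULL) {
  default <- c(
    "never" = 0,
    "1-3/month" = 2 / 30.4,
    "1/week" = 1 / 7,
    "2-4/week" = 3 / 7,
    "5-6/week" = 5.5 / 7,
    "1/day" = 1,
    "2-3/day" = 2.5,
    "4-6/day" = 5,
    ">=6/day" = 6
  )
  if (is.null(midpoints)) {
    return(default)
  }
  if (is.null(names(midpoints)) || !all(names(midpoints) %in% names(default))) {
    stop("midpoint overrides must be named with FFQ category labels", call. = FALSE)
  }
  default[names(midpoints)] <- midpoints
  default
}

#' Convert an FFQ frequency category to servings per day
#'
#' @param category Character vector of category labels (see
#'   [ffq_frequency_levels()]).
#' @param midpoints Optional midpoint overrides, passed on.
#' @return Numeric vector of servings/day, full precision.
#' @examples
#' frequency_to_per_day("5-6/week")  # 5.5/7 = 0.7857...
#' @export
frequency_to_per_day <- function(category, midpoints = NULL) {
  levels <- ffq_frequency_levels(midpoints)
  unknown <- setdiff(unique(category), names(levels))
  if (length(unknown) > 0) {
    stop("unknown FFQ frequency category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(levels[category])
}

#' Format servings/day in the questionnaire's printed convention
#'
#' Display truncates (floors) at two decimals, so 5.5 times/week = 0.7857.../d
#' prints as "0.78". Truncation is a formatting convention only; all
#' computation keeps full precision.
#'
#' @param x Numeric vector of servings/day.
#' @return Character vector, two decimals, truncated.
#' @export
format_servings <- function(x) {
  sprintf("%.2f", floor(x * 100) / 100)
}

#' Compute a daily nutrient profile from FFQ responses
#'
#' Each item's servings/day (from its frequency category) is multiplied by the
#' nutrient content of its specified portion and summed over items; optional
#' micronutrient supplements are added. Macronutrients are additionally
#' expressed as percentage of total energy (%TE) using Atwater factors of
#' 4 kcal/g for carbohydrate and protein, 9 kcal/g for fat and 7 kcal/g for
#' alcohol. Glycaemic index is the carbohydrate-intake-weighted mean of the
#' per-item values.
#'
#' @param responses Data frame with columns `item_id` and `category` (one row
#'   per FFQ item; exactly one response per item).
#' @param fct Food-composition table, see [default_food_composition()]:
#'   one row per `item_id` with per-portion `energy_kcal`, nutrient columns
#'   and `gi`.
#' @param supplements Optional named numeric vector of daily supplement
#'   intakes, names matching nutrient columns of `fct`; must be non-negative.
#' @param midpoints Optional FFQ midpoint overrides.
#' @return Named list: `energy_kcal`, every nutrient in intake units/day,
#'   `gi`, and `carbohydrate_pte`, `protein_pte`, `fat_pte`, `alcohol_pte`.
#' @export
compute_nutrient_profile <- function(responses, fct, supplements = NULL,
                                     midpoints = NULL) {
  stopifnot(is.data.frame(responses), is.data.frame(fct))
  missing_items <- setdiff(responses$item_id, fct$item_id)
  if (length(missing_items) > 0) {
    stop("FFQ items absent from the food-composition table: ",
         paste(utils::head(missing_items, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(responses$item_id)) {
    stop("duplicate FFQ item responses", call. = FALSE)
  }
  freq <- frequency_to_per_day(responses$category, midpoints)
  idx <- match(responses$item_id, fct$item_id)
  nutrient_cols <- fct_nutrient_columns(fct)
  mat <- as.matrix(fct[idx, nutrient_cols, drop = FALSE])
  totals <- as.list(colSums(mat * freq))

  if (!is.null(supplements)) {
    if (any(supplements < 0)) {
      stop("supplement intakes must be non-negative", call. = FALSE)
    }
    bad <- setdiff(names(supplements), nutrient_cols)
    if (length(bad) > 0) {
      stop("unknown supplement nutrients: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(supplements)) {
      totals[[nm]] <- totals[[nm]] + supplements[[nm]]
    }
  }

  # carbohydrate-weighted glycaemic index of the foods actually eaten
  carb_by_item <- fct$carbohydrate_g[idx] * freq
  totals$gi <- if (sum(carb_by_item) > 0) {
    sum(fct$gi[idx] * carb_by_item) / sum(carb_by_item)
  } else {
    0
  }

  e <- totals$energy_kcal
  pte <- function(gram, kcal_per_g) {
    if (e > 0) 100 * gram * kcal_per_g / e else 0
  }
  totals$carbohydrate_pte <- pte(totals$carbohydrate_g, 4)
  totals$protein_pte <- pte(totals$protein_g, 4)
  totals$fat_pte <- pte(totals$fat_g, 9)
  totals$alcohol_pte <- pte(totals$alcohol_g, 7)
  totals
}

# nutrient columns = everything except identifiers, portion size, food group
# and the per-item glycaemic index (which is intake-weighted, not summed)
fct_nutrient_columns <- function(fct) {
  setdiff(names(fct), c("item_id", "item", "food_group", "portion_g", "gi"))
}

#' Daily food-group intakes in grams from FFQ responses
#'
#' @inheritParams compute_nutrient_profile
#' @return Named numeric vector of g/day (ml/day for drinks) per food group.
#' @export
compute_food_groups <- function(responses, fct, midpoints = NULL) {
  freq <- frequency_to_per_day(responses$category, midpoints)
  idx <- match(responses$item_id, fct$item_id)
  grams <- fct$portion_g[idx] * freq
  tapply(grams, factor(fct$food_group[idx], levels = unique(fct$food_group)),
         sum, default = 0)
}

#' Extreme-energy exclusion rule
#'
#' Participants with implausible total energy intakes are excluded: below
#' 500 or above 3500 kcal/day in women, below 800 or above 4000 kcal/day in
#' men. Boundaries are inclusive (the rule excludes strictly outside the
#' interval).
#'
#' @param energy_kcal Numeric vector of daily energy intakes; `NA` is treated
#'   as missing FFQ information (excluded at the missing-FFQ stage, not here).
#' @param sex Character vector, `"male"` or `"female"`.
#' @return Logical vector: `TRUE` = keep.
#' @export
energy_exclusion <- function(energy_kcal, sex) {
  sex <- match.arg_vec(sex, c("male", "female"))
  lo <- ifelse(sex == "female", 500, 800)
  hi <- ifelse(sex == "female", 3500, 4000)
  ifelse(is.na(energy_kcal), NA, energy_kcal >= lo & energy_kcal <= hi)
}

match.arg_vec <- function(x, choices) {
  if (!all(x %in% choices)) {
    stop("values must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Default 17-item Mediterranean diet adherence criteria
#'
#' One row per item: a predicate over daily food-group (g/d) or nutrient
#' intakes, scored 1 when met. Thresholds are an editable convention modelled
#' on the energy-restricted Mediterranean diet screener used in Spanish
#' prevention trials; they are configuration, not measurements.
#'
#' @return Data frame with columns `item`, `description`, `variable`,
#'   `op` (`">="` or `"<="`) and `threshold` (g/d unless noted).
#' @export
md17_criteria_default <- function() {
  data.frame(
    item = 1:17,
    description = c(
      "Olive oil as the main culinary fat (>= 30 g/d)",
      "Olive oil >= 4 tablespoons/d (>= 40 g/d)",
      "Vegetables >= 2 servings/d (>= 250 g/d)",
      "Fruit >= 3 servings/d (>= 360 g/d)",
      "Whole-grain cereals >= 1 serving/d (>= 25 g/d)",
      "Red meat < 1 serving/d (<= 70 g/d)",
      "Processed meat < 1 serving/d (<= 30 g/d)",
      "Butter/margarine/cream (other fats) < 1 serving/d (<= 10 g/d)",
      "Sugary drinks and dairy desserts < 1 serving/d (<= 100 g/d)",
      "Legumes >= 3 servings/week (>= 20 g/d)",
      "Fish/seafood >= 3 servings/week (>= 60 g/d)",
      "Commercial sweets < 3 servings/week (<= 15 g/d)",
      "Nuts >= 3 servings/week (>= 12 g/d)",
      "White meat preferred over red (white meat >= 50 g/d)",
      "Refined cereals limited (<= 150 g/d)",
      "Wine in moderation (<= 200 ml/d)",
      "Spirits avoided (<= 5 ml/d)"
    ),
    variable = c(
      "olive_oil", "olive_oil", "vegetables", "fruits", "whole_cereals",
      "red_meat", "processed_meat", "other_oils", "dairy_desserts",
      "legumes", "fish_seafood", "cookies_sweets", "nuts", "white_meat",
      "refined_cereals", "wine", "spirits"
    ),
    op = c(
      ">=", ">=", ">=", ">=", ">=", "<=", "<=", "<=", "<=", ">=", ">=",
      "<=", ">=", ">=", "<=", "<=", "<="
    ),
    threshold = c(30, 40, 250, 360, 25, 70, 30, 10, 100, 20, 60, 15, 12, 50,
                  150, 200, 5),
    stringsAsFactors = FALSE
  )
}

#' Score 17-item Mediterranean diet adherence
#'
#' Sums the met-item indicators over the 17 food-habit criteria; the total
#' ranges from 0 (no adherence) to 17 (maximum adherence).
#'
#' @param intakes Named numeric vector (or single-row data frame) of daily
#'   food-group/nutrient intakes covering every `variable` in `criteria`.
#' @param criteria Criteria table, default [md17_criteria_default()].
#' @return Integer in 0..17, or `NA` if any criterion is unevaluable.
#' @export
score_md17 <- function(intakes, criteria = md17_criteria_default()) {
  if (is.data.frame(intakes)) intakes <- unlist(intakes[1, , drop = TRUE])
  if (nrow(criteria) != 17) {
    stop("MD adherence criteria must have exactly 17 items", call. = FALSE)
  }
  vals <- intakes[criteria$variable]
  if (anyNA(vals)) {
    return(NA_integer_)
  }
  met <- ifelse(criteria$op == ">=", vals >= criteria$threshold,
                vals <= criteria$threshold)
  as.integer(sum(met))
}

#' Default dietary inflammatory index parameter table
#'
#' Thirty food parameters (nutrients, whole foods and bioactive compounds)
#' with a global reference mean and standard deviation of daily intake and a
#' signed literature-derived inflammatory effect score (positive =
#' pro-inflammatory, negative = anti-inflammatory). The reference means/SDs
#' shipped here are synthetic, plausible values for documentation and testing;
#' substitute the published global reference database for real analyses.
#'
#' @return Data frame: `parameter`, `intake_variable` (name in the nutrient
#'   profile / food groups), `global_mean`, `global_sd`, `effect_score`.
#' @export
dii_parameters_default <- function() {
  p <- data.frame(
    parameter = c(
      "alcohol", "carbohydrate", "cholesterol", "energy", "iron", "fibre",
      "folic_acid", "garlic", "tea", "magnesium", "mufa", "omega3", "omega6",
      "niacin", "onion", "protein", "pufa", "riboflavin", "sfa", "selenium",
      "thiamine", "total_fat", "trans_fat", "vitamin_a", "vitamin_b12",
      "vitamin_b6", "vitamin_c", "vitamin_d", "vitamin_e", "zinc"
    ),
    intake_variable = c(
      "alcohol_g", "carbohydrate_g", "cholesterol_mg", "energy_kcal",
      "iron_mg", "fibre_g", "vitamin_b9_ug", "garlic", "tea", "magnesium_mg",
      "mufa_g", "omega3_g", "linoleic_g", "vitamin_b3_mg", "onion",
      "protein_g", "pufa_g", "vitamin_b2_mg", "sfa_g", "selenium_ug",
      "vitamin_b1_mg", "fat_g", "trans_g", "vitamin_a_ug", "vitamin_b12_ug",
      "vitamin_b6_mg", "vitamin_c_mg", "vitamin_d_ug", "vitamin_e_mg",
      "zinc_mg"
    ),
    global_mean = c(
      11, 241, 383, 2366, 16.5, 26.2, 352, 3, 30, 421, 53.6, 2.37, 13.6,
      40.8, 30, 99.4, 16.8, 2.0, 26.3, 117, 1.6, 103.8, 0.6, 1110, 10, 2.37,
      202, 6.2, 10.6, 13.2
    ),
    global_sd = c(
      15, 40, 117, 550, 4, 8.8, 103, 2, 20, 109, 12, 0.95, 5.6, 10, 18, 17,
      5, 0.65, 7, 33, 0.4, 20, 0.4, 640, 4.5, 0.6, 86, 3.5, 4, 3.3
    ),
    effect_score = c(
      -0.278, 0.097, 0.110, 0.180, 0.032, -0.663, -0.190, -0.412, -0.536,
      -0.484, -0.009, -0.436, -0.159, -0.246, -0.301, 0.021, -0.337, -0.068,
      0.373, -0.191, -0.098, 0.298, 0.229, -0.401, 0.106, -0.365, -0.424,
      -0.446, -0.419, -0.313
    ),
    stringsAsFactors = FALSE
  )
  stopifnot(all(p$global_sd > 0), !anyDuplicated(p$parameter))
  p
}

#' Compute the dietary inflammatory index
#'
#' For each food parameter the daily intake is standardized against a global
#' reference (z = (intake - mean)/sd), converted to a centred percentile score
#' c = 2*Phi(z) - 1 in (-1, 1), multiplied by the parameter's inflammatory
#' effect score, and summed. Positive totals indicate a pro-inflammatory
#' diet; by construction |DII| < sum of |effect scores|.
#'
#' The percentile is the standard-normal CDF of the z-score by default, which
#' matches the reference-database construction; an empirical mode computes
#' percentiles within a supplied cohort of intakes instead.
#'
#' @param intakes Named numeric vector of daily intakes (nutrient profile plus
#'   whole-food groups) covering every `intake_variable` of `parameters`.
#' @param parameters Parameter table, default [dii_parameters_default()].
#' @param percentile `"normal"` (default) or `"empirical"`.
#' @param cohort_intakes For `percentile = "empirical"`, a matrix/data frame
#'   of intakes (rows = subjects) used as the percentile reference.
#' @return Numeric DII score.
#' @export
compute_dii <- function(intakes, parameters = dii_parameters_default(),
                        percentile = c("normal", "empirical"),
                        cohort_intakes = NULL) {
  percentile <- match.arg(percentile)
  if (is.data.frame(intakes)) intakes <- unlist(intakes[1, , drop = TRUE])
  vars <- parameters$intake_variable
  unresolved <- vars[!(vars %in% names(intakes))]
  if (length(unresolved) > 0) {
    stop("DII parameters with no intake mapping: ",
         paste(parameters$parameter[match(unresolved, vars)], collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(intakes[vars])
  if (percentile == "normal") {
    z <- (x - parameters$global_mean) / parameters$global_sd
    p <- stats::pnorm(z)
  } else {
    if (is.null(cohort_intakes)) {
      stop("empirical percentiles require cohort_intakes", call. = FALSE)
    }
    p <- vapply(seq_along(vars), function(j) {
      ref <- cohort_intakes[[vars[j]]]
      stats::ecdf(ref)(x[j])
    }, numeric(1))
  }
  sum((2 * p - 1) * parameters$effect_score)
}
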
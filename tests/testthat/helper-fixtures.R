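# shared fixtures built in code

# a clinical panel sitting exactly on the harmonized thresholds
panel_at_thresholds <- function(sex = "male") {
  cfg <- metsss_config()
  thr <- if (sex == "male") cfg$thresholds_male else cfg$thresholds_female
  data.frame(sex = sex, bmi = 29, wc = thr[["wc"]], tag = thr[["tag"]],
             hdl = thr[["hdl"]], sbp = thr[["sbp"]], dbp = thr[["dbp"]],
             glucose = thr[["glucose"]])
}

# a tiny two-item composition table with round numbers
toy_fct <- function() {
  data.frame(
    item_id = 1:2, item = c("a", "b"), food_group = c("ga", "gb"),
    portion_g = c(50, 100),
    energy_kcal = c(98, 200), carbohydrate_g = c(0, 30), protein_g = c(2, 5),
    fat_g = c(10, 5), sfa_g = c(2, 1), mufa_g = c(5, 2), pufa_g = c(3, 2),
    trans_g = c(0, 0), linoleic_g = c(1, 1), omega3_g = c(0.1, 0.1),
    cholesterol_mg = c(10, 0), fibre_g = c(0, 2), alcohol_g = c(0, 0),
    iodine_ug = c(200, 0), gi = c(0, 55)
  )
}

# intakes meeting every default MD adherence criterion
md17_full_intakes <- function() {
  c(olive_oil = 45, vegetables = 300, fruits = 400, whole_cereals = 30,
    red_meat = 30, processed_meat = 10, other_oils = 2, dairy_desserts = 20,
    legumes = 25, fish_seafood = 100, cookies_sweets = 5, nuts = 20,
    white_meat = 60, refined_cereals = 80, wine = 100, spirits = 0)
}

# small null spec for calibration-style tests
tiny_null_spec <- function(n = 300, seed = 1) {
  null_spec(cohort_spec(n_subjects = n, seed = seed))
}

full_covariates <- c("sex", "age", "education", "smoking", "marital",
                     "employment")
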
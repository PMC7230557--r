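# Rendering of the five tertile-comparison tables: three tertile columns of
# mean +/- SD and median (IQR) (or n (%)), three p-value columns (unadjusted
# ANOVA, sex/age-adjusted, fully adjusted) and superscript letters for the
# Bonferroni pairwise contrasts that reach p < 0.05 under full adjustment
# (a: T1 vs T2, b: T1 vs T3, c: T2 vs T3).

covariate_sets <- function() {
  full <- c("sex", "age", "education", "smoking", "marital", "employment")
  meds <- c("med_antihypertensive", "med_cholesterol", "med_insulin",
            "med_oral_hypoglycaemic", "med_aspirin")
  list(none = character(0), sex_age = c("sex", "age"), full = full,
       full_meds = c(full, meds))
}

format_p <- function(p, digits = 3) {
  ifelse(is.na(p), "", ifelse(p < 10^(-digits),
                              paste0("<", format(10^(-digits))),
                              formatC(p, digits = digits, format = "f")))
}

pairwise_letters <- function(pw, gate_p) {
  if (is.na(gate_p) || gate_p >= 0.05) return("")
  letters_map <- c("T1 vs T2" = "a", "T1 vs T3" = "b", "T2 vs T3" = "c")
  paste(letters_map[pw$pair[pw$flag]], collapse = ",")
}

quantitative_row <- function(data, var, label, full_covariates,
                             digits = 1) {
  desc <- describe_by_tertile(data[[var]], data$tertile)
  fmt <- function(g) {
    r <- desc[desc$tertile == g, ]
    sprintf("%.*f ± %.*f | %.*f (%.*f)", digits, r$mean, digits, r$sd,
            digits, r$median, digits, r$iqr)
  }
  t_un <- test_quantitative(data, var, covariates = character(0))
  t_sa <- test_quantitative(data, var, covariates = c("sex", "age"))
  t_fu <- test_quantitative(data, var, covariates = full_covariates)
  data.frame(
    variable = label,
    T1 = fmt("T1"), T2 = fmt("T2"), T3 = fmt("T3"),
    p = format_p(t_un$p), p_sex_age = format_p(t_sa$p),
    p_full = format_p(t_fu$p),
    pairwise = pairwise_letters(t_fu$pairwise, t_fu$p),
    stringsAsFactors = FALSE
  )
}

categorical_row <- function(data, var, label, positive = NULL) {
  x <- data[[var]]
  if (!is.null(positive)) x <- factor(ifelse(x %in% positive, "yes", "no"),
                                      levels = c("no", "yes"))
  tst <- test_categorical(x, data$tertile)
  desc <- describe_by_tertile(x, data$tertile)
  lv <- if (!is.null(positive)) "yes" else levels(as.factor(x))
  rows <- lapply(lv, function(l) {
    fmt <- vapply(c("T1", "T2", "T3"), function(g) {
      r <- desc[desc$tertile == g & desc$level == l, ]
      sprintf("%d (%.1f)", r$n, r$pct)
    }, "")
    data.frame(variable = if (length(lv) == 1) label else
      paste0(label, ": ", l),
      T1 = fmt[1], T2 = fmt[2], T3 = fmt[3],
      p = format_p(tst$p), p_sex_age = "", p_full = "", pairwise = "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

nonparametric_row <- function(data, var, label, digits = 1) {
  desc <- describe_by_tertile(data[[var]], data$tertile)
  fmt <- function(g) {
    r <- desc[desc$tertile == g, ]
    sprintf("%.*f ± %.*f", digits, r$mean, digits, r$sd)
  }
  tst <- test_nonparametric(data[[var]], data$tertile)
  data.frame(variable = label, T1 = fmt("T1"), T2 = fmt("T2"), T3 = fmt("T3"),
             p = format_p(tst$p), p_sex_age = "", p_full = "",
             pairwise = pairwise_letters(tst$pairwise, tst$p),
             stringsAsFactors = FALSE)
}

#' Build the five tertile-comparison tables
#'
#' Regenerates the study's table layout from an analysed (scored, excluded,
#' tertile-assigned) subject table: general characteristics (chi-square,
#' Kruskal-Wallis for age), cardiovascular risk factors and depression
#' (ANOVA/ANCOVA, medication among the full covariates), physical activity
#' and sedentary behaviour, nutrient intakes, and food groups with the
#' dietary inflammatory index and Mediterranean diet adherence.
#'
#' @param analysed Subject table with a `tertile` factor (see
#'   [analyse_cohort()]).
#' @return Named list of data frames `table1`..`table5`.
#' @export
build_tables <- function(analysed) {
  cs <- covariate_sets()
  d <- analysed

  t1 <- rbind(
    categorical_row(d, "sex", "Women, n (%)", positive = "female"),
    nonparametric_row(d, "age", "Age, years"),
    categorical_row(d, "obesity", "Prevalence of obesity, n (%)",
                    positive = TRUE),
    categorical_row(d, "education", "Education level, n (%)"),
    categorical_row(d, "smoking", "Smoking habit, n (%)"),
    categorical_row(d, "marital", "Marital status, n (%)"),
    categorical_row(d, "employment", "Employment status, n (%)"),
    categorical_row(d, "high_bp", "High blood pressure, n (%)",
                    positive = TRUE),
    categorical_row(d, "hyperglycaemia", "Hyperglycaemia, n (%)",
                    positive = TRUE),
    categorical_row(d, "hypertriglyceridemia", "Hypertriglyceridemia, n (%)",
                    positive = TRUE),
    categorical_row(d, "low_hdl", "Low HDL-cholesterol, n (%)",
                    positive = TRUE),
    categorical_row(d, "abdominal_obesity", "Abdominal obesity, n (%)",
                    positive = TRUE),
    categorical_row(d, "med_antihypertensive", "Antihypertensive agents, n (%)",
                    positive = TRUE),
    categorical_row(d, "med_cholesterol", "Anti-cholesterol agents, n (%)",
                    positive = TRUE),
    categorical_row(d, "med_insulin", "Insulin, n (%)", positive = TRUE),
    categorical_row(d, "med_oral_hypoglycaemic",
                    "Oral hypoglycaemic agents, n (%)", positive = TRUE),
    categorical_row(d, "med_aspirin", "Aspirin or antiplatelet drugs, n (%)",
                    positive = TRUE)
  )

  t2_vars <- c(
    "Weight, kg" = "weight", "BMI, kg/m2" = "bmi",
    "Waist circumference, cm" = "wc", "Glucose, mg/dL" = "glucose",
    "Glycated haemoglobin, %" = "hba1c",
    "Total cholesterol, mg/dL" = "tc", "HDL-cholesterol, mg/dL" = "hdl",
    "LDL-cholesterol, mg/dL" = "ldl", "Triglycerides, mg/dL" = "tag",
    "Systolic blood pressure, mmHg" = "sbp",
    "Diastolic blood pressure, mmHg" = "dbp", "Heart rate, bpm" = "hr",
    "Visceral adiposity index" = "vai",
    "Beck Depression Inventory-II" = "bdi_score"
  )
  t2 <- do.call(rbind, lapply(names(t2_vars), function(lab) {
    quantitative_row(d, t2_vars[[lab]], lab, cs$full_meds)
  }))

  t3_vars <- c(
    "Sedentary time, h/d" = "sedentary_h", "TV-viewing time, h/d" = "tv_h",
    "Sleeping time, h/d" = "sleep_h", "Total LTPA, MET-min/d" = "ltpa_total",
    "Light LTPA, MET-min/d" = "ltpa_light",
    "Moderate LTPA, MET-min/d" = "ltpa_moderate",
    "Vigorous LTPA, MET-min/d" = "ltpa_vigorous",
    "30-s chair stand test, n" = "chair_stand"
  )
  t3 <- do.call(rbind, lapply(names(t3_vars), function(lab) {
    quantitative_row(d, t3_vars[[lab]], lab, cs$full)
  }))

  t4_vars <- c(
    "Total energy, kcal/d" = "energy_kcal", "Total fat, %TE" = "fat_pte",
    "MUFA, %TE" = "mufa_pte", "PUFA, %TE" = "pufa_pte",
    "SFA, %TE" = "sfa_pte", "Trans FA, g/d" = "trans_g",
    "Linoleic acid, g/d" = "linoleic_g", "w-3 FA, g/d" = "omega3_g",
    "Carbohydrate, %TE" = "carbohydrate_pte", "Glycaemic index" = "gi",
    "Protein, %TE" = "protein_pte", "Cholesterol, mg/d" = "cholesterol_mg",
    "Fibre, g/d" = "fibre_g", "Alcohol, g/d" = "alcohol_g",
    "Vitamin A, ug/d" = "vitamin_a_ug", "Vitamin B1, mg/d" = "vitamin_b1_mg",
    "Vitamin B2, mg/d" = "vitamin_b2_mg", "Vitamin B3, mg/d" = "vitamin_b3_mg",
    "Vitamin B6, mg/d" = "vitamin_b6_mg", "Vitamin B9, ug/d" = "vitamin_b9_ug",
    "Vitamin B12, ug/d" = "vitamin_b12_ug", "Vitamin C, mg/d" = "vitamin_c_mg",
    "Vitamin D, ug/d" = "vitamin_d_ug", "Vitamin E, mg/d" = "vitamin_e_mg",
    "Calcium, mg/d" = "calcium_mg", "Phosphorus, mg/d" = "phosphorus_mg",
    "Magnesium, mg/d" = "magnesium_mg", "Iron, mg/d" = "iron_mg",
    "Iodine, ug/d" = "iodine_ug", "Potassium, mg/d" = "potassium_mg",
    "Selenium, ug/d" = "selenium_ug", "Zinc, mg/d" = "zinc_mg",
    "Sodium, mg/d" = "sodium_mg"
  )
  t4 <- do.call(rbind, lapply(names(t4_vars), function(lab) {
    quantitative_row(d, t4_vars[[lab]], lab, cs$full)
  }))

  t5_vars <- c(
    "Fruits, g/d" = "fruits", "Vegetables, g/d" = "vegetables",
    "Potatoes and tubers, g/d" = "potatoes", "Legumes, g/d" = "legumes",
    "Nuts, g/d" = "nuts", "Whole cereals, g/d" = "whole_cereals",
    "Refined cereals, g/d" = "refined_cereals",
    "White fish, g/d" = "white_fish", "Bluefish, g/d" = "bluefish",
    "Seafood, g/d" = "seafood", "Red meat, g/d" = "red_meat",
    "White meat, g/d" = "white_meat", "Processed meat, g/d" = "processed_meat",
    "Viscera, g/d" = "viscera", "Eggs, g/d" = "eggs",
    "Whole-fat dairy, g/d" = "whole_dairy",
    "Skimmed dairy, g/d" = "skimmed_dairy", "Cheese, g/d" = "cheese",
    "Dairy desserts, g/d" = "dairy_desserts",
    "Cookies and sweets, g/d" = "cookies_sweets",
    "Olive oil, g/d" = "olive_oil", "Other oils and fats, g/d" = "other_oils",
    "Snacks, g/d" = "snacks", "Wine, ml/d" = "wine", "Beer, ml/d" = "beer",
    "Spirits, ml/d" = "spirits",
    "Dietary Inflammatory Index" = "dii",
    "Mediterranean Diet Adherence" = "md17"
  )
  t5 <- do.call(rbind, lapply(names(t5_vars), function(lab) {
    quantitative_row(d, t5_vars[[lab]], lab, cs$full)
  }))

  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4, table5 = t5)
}
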
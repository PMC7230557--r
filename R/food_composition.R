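# Synthetic food-composition matrix for the 143-item FFQ.
#
# One row per FFQ item: typical portion, food-group membership, per-100 g
# nutrient densities expanded to per-portion contents, and a glycaemic index.
# Values are plausible Mediterranean-diet magnitudes authored for simulation
# and testing; they are NOT a transcription of any national composition
# database (reproducing one is explicitly out of scope). Items within a group
# share the group's density profile with a deterministic +/-20% spread.

# per-100 g (or per-100 ml for drinks) density templates by food group
food_group_templates <- function() {
  cols <- c(
    "n_items", "portion_g", "group_daily_g", "kcal", "carb", "prot", "fat",
    "sfa", "mufa", "pufa", "trans", "linoleic", "omega3", "chol_mg", "fibre",
    "alcohol", "vita_ug", "b1_mg", "b2_mg", "b3_mg", "b6_mg", "b9_ug",
    "b12_ug", "c_mg", "d_ug", "e_mg", "ca_mg", "p_mg", "mg_mg", "fe_mg",
    "iodine_ug", "k_mg", "se_ug", "zn_mg", "na_mg", "gi"
  )
  m <- rbind(
    fruits          = c(16, 150, 355, 52, 12.0, 0.8, 0.3, 0.05, 0.05, 0.10, 0, 0.05, 0.02,   0, 2.2, 0,  45, 0.04, 0.04, 0.5, 0.08, 18, 0,  35, 0,   0.6,  15,  20, 12, 0.4,  2, 200, 0.5, 0.2,   2, 45),
    vegetables      = c(18, 120, 327, 30, 5.0, 1.8, 0.3, 0.05, 0.03, 0.12, 0, 0.06, 0.03,   0, 2.6, 0, 180, 0.07, 0.07, 0.8, 0.15, 60, 0,  35, 0,   1.0,  45,  45, 18, 0.9,  3, 280, 0.8, 0.4,  15, 35),
    potatoes        = c( 2, 150,  65, 80, 18.0, 2.0, 0.1, 0.03, 0.01, 0.05, 0, 0.03, 0.01,   0, 1.8, 0,   1, 0.09, 0.03, 1.2, 0.25, 18, 0,  12, 0,   0.1,  10,  50, 22, 0.7,  3, 420, 0.6, 0.4,   8, 75),
    legumes         = c( 5,  60,  21, 320, 50.0, 21.0, 2.5, 0.5, 0.6, 1.2, 0, 1.0, 0.2,   0, 15.0, 0,   3, 0.45, 0.18, 2.2, 0.40, 280, 0, 3, 0,   0.8, 110, 380, 140, 6.5, 10, 1100, 8.0, 3.2,  12, 30),
    nuts            = c( 4,  30,  15.5, 600, 10.0, 20.0, 52.0, 6.0, 30.0, 14.0, 0, 11.0, 2.0,   0, 8.0, 0,   3, 0.35, 0.20, 4.0, 0.45, 65, 0,   1, 0,  12.0, 120, 420, 180, 3.5,  8, 650, 8.0, 3.0,   3, 20),
    whole_cereals   = c( 4,  50,  42, 300, 55.0, 10.0, 3.0, 0.6, 0.8, 1.4, 0, 1.1, 0.1,   0, 9.0, 0,   0, 0.40, 0.15, 8.0, 0.30, 50, 0,   0, 0,   1.5,  35, 300, 110, 3.5,  5, 300, 30.0, 2.5, 350, 50),
    refined_cereals = c(10,  60, 109, 290, 58.0, 9.0, 1.8, 0.4, 0.4, 0.8, 0.02, 0.6, 0.05,  0, 3.2, 0,   0, 0.15, 0.08, 3.0, 0.10, 25, 0,   0, 0,   0.4,  25, 110, 28, 1.2,  4, 130, 12.0, 1.0, 420, 72),
    white_fish      = c( 5, 130,  40, 85, 0, 18.0, 1.2, 0.3, 0.3, 0.4, 0, 0.05, 0.30,  55, 0, 0,  10, 0.07, 0.08, 4.5, 0.30, 12, 1.8, 0, 1.8, 0.5,  25, 210, 28, 0.7, 30, 330, 35.0, 0.5,  90, 0),
    bluefish        = c( 5, 120,  34, 185, 0, 20.0, 11.5, 2.8, 4.0, 3.5, 0, 0.4, 2.60,  70, 0, 0,  35, 0.10, 0.25, 9.0, 0.50, 10, 8.5, 0, 9.0, 1.2,  30, 250, 30, 1.1, 35, 360, 40.0, 0.8,  95, 0),
    seafood         = c( 5,  80,  28, 90, 1.5, 17.0, 1.6, 0.4, 0.4, 0.6, 0, 0.05, 0.40, 130, 0, 0,  55, 0.05, 0.10, 2.5, 0.12, 16, 4.0, 1, 0.5, 1.2,  60, 220, 42, 2.3, 90, 260, 40.0, 2.8, 280, 0),
    red_meat        = c( 6, 125,  49, 220, 0, 20.0, 15.0, 6.0, 6.8, 1.0, 0.35, 0.6, 0.10,  72, 0, 0,   8, 0.08, 0.20, 8.0, 0.35,  8, 2.2, 0, 0.4, 0.4,  10, 190, 21, 2.2,  6, 320, 10.0, 4.5,  70, 0),
    white_meat      = c( 5, 130,  62, 150, 0, 21.0, 7.0, 2.0, 3.0, 1.5, 0.05, 1.2, 0.10,  75, 0, 0,  15, 0.07, 0.15, 10.0, 0.45, 10, 0.4, 0, 0.2, 0.3,  12, 200, 24, 1.0,  5, 300, 12.0, 1.5,  80, 0),
    processed_meat  = c( 7,  50,  34, 320, 1.5, 15.0, 28.0, 10.0, 13.0, 3.0, 0.50, 2.4, 0.20,  70, 0, 0,   5, 0.25, 0.15, 4.0, 0.20,  3, 1.5, 0, 0.6, 0.3,  12, 180, 16, 1.4, 10, 230, 15.0, 2.2, 1100, 0),
    viscera         = c( 2, 100,   2.2, 130, 2.0, 19.0, 5.0, 1.8, 1.2, 1.0, 0.05, 0.4, 0.05, 320, 0, 0, 7000, 0.25, 2.50, 12.0, 0.80, 250, 55, 20, 1.0, 0.5,  10, 340, 20, 7.0, 12, 300, 50.0, 4.0,  90, 0),
    eggs            = c( 1,  55,  24, 145, 0.7, 12.5, 10.0, 3.0, 4.0, 1.5, 0.05, 1.2, 0.10, 370, 0, 0, 160, 0.10, 0.40, 0.1, 0.12, 50, 2.0, 0, 1.8, 1.1,  55, 200, 12, 1.9, 50, 130, 30.0, 1.3, 140, 0),
    whole_dairy     = c( 4, 200,  45, 65, 4.7, 3.3, 3.6, 2.3, 1.0, 0.1, 0.10, 0.08, 0.05,  14, 0, 0,  45, 0.04, 0.18, 0.1, 0.05,  5, 0.4, 1, 0.1, 0.1, 120,  95, 11, 0.1, 18, 150, 1.5, 0.4,  50, 30),
    skimmed_dairy   = c( 4, 200, 150, 40, 4.9, 3.4, 0.3, 0.2, 0.1, 0.0, 0, 0.01, 0.01,   3, 0, 0,  25, 0.04, 0.18, 0.1, 0.05,  5, 0.4, 1, 0.1, 0.0, 125, 100, 11, 0.1, 18, 155, 1.5, 0.4,  52, 30),
    cheese          = c( 4,  40,  30, 350, 1.5, 25.0, 27.0, 17.0, 7.5, 0.8, 0.80, 0.5, 0.10,  90, 0, 0, 270, 0.03, 0.40, 0.1, 0.08, 20, 1.5, 0, 0.5, 0.6, 740, 500, 28, 0.5, 40, 100, 14.0, 3.0, 650, 0),
    dairy_desserts  = c( 4, 125,  15, 120, 18.0, 3.5, 3.8, 2.4, 1.1, 0.2, 0.10, 0.1, 0.02,  13, 0.2, 0,  35, 0.04, 0.20, 0.2, 0.05,  8, 0.3, 1, 0.2, 0.2, 130, 110, 13, 0.2, 20, 170, 2.0, 0.5,  70, 60),
    cookies_sweets  = c(10,  40,  27, 450, 62.0, 6.0, 20.0, 9.0, 7.0, 3.0, 1.20, 2.4, 0.10,  35, 2.0, 0,  60, 0.08, 0.10, 1.0, 0.05, 12, 0.6, 0, 0.8, 1.5,  60, 120, 30, 1.8,  8, 180, 4.0, 0.8, 280, 68),
    olive_oil       = c( 2,  10,  39, 884, 0, 0, 100.0, 14.0, 73.0, 10.5, 0, 9.5, 0.70,   0, 0, 0,   0, 0, 0, 0, 0, 0, 0, 0, 0,  14.0,   0,   0,  0, 0.1,  0,   1, 0, 0,   1, 0),
    other_oils      = c( 3,  10,   3.0, 800, 0.5, 0.3, 87.0, 32.0, 25.0, 25.0, 2.50, 20.0, 0.40,  60, 0, 0, 400, 0, 0.01, 0, 0, 1, 0.1, 0, 0.6, 6.0,  15,  10,  1, 0.1,  2,  20, 0.5, 0,  90, 0),
    snacks          = c( 7,  50,  11, 450, 48.0, 7.0, 24.0, 7.0, 10.0, 5.5, 0.60, 4.5, 0.10,  15, 2.5, 0,  20, 0.12, 0.08, 2.5, 0.20, 25, 0.3, 5, 0.2, 2.5,  40, 150, 40, 1.5,  8, 500, 5.0, 1.0, 700, 65),
    wine            = c( 2, 100,  59, 78, 2.0, 0.1, 0, 0, 0, 0, 0, 0, 0,   0, 0, 9.5,   0, 0, 0.01, 0.1, 0.03, 1, 0, 0, 0, 0,   8,  15, 10, 0.5,  1, 100, 0.2, 0.1,   4, 0),
    beer            = c( 2, 200, 112, 45, 3.6, 0.4, 0, 0, 0, 0, 0, 0, 0,   0, 0, 3.9,   0, 0.01, 0.03, 0.6, 0.05, 6, 0.1, 0, 0, 0,   5,  25, 9, 0.1,  1,  35, 0.5, 0.1,   4, 0),
    spirits         = c( 3,  40,   3.5, 240, 0.5, 0, 0, 0, 0, 0, 0, 0, 0,   0, 0, 33.0,   0, 0, 0, 0, 0, 0, 0, 0, 0, 0,   0,   2,  1, 0.0,  0,   2, 0, 0,   1, 0),
    garlic          = c( 1,   5,   3.0, 140, 30.0, 6.0, 0.5, 0.1, 0.0, 0.2, 0, 0.1, 0.02,   0, 2.0, 0,   0, 0.20, 0.10, 0.7, 1.20,  3, 0, 30, 0, 0.1, 180, 150, 25, 1.7,  5, 400, 14.0, 1.2,  17, 30),
    onion           = c( 1,  60,  30, 38, 8.0, 1.1, 0.1, 0.02, 0.01, 0.03, 0, 0.01, 0.00,   0, 1.7, 0,   0, 0.05, 0.03, 0.1, 0.12, 19, 0,   7, 0, 0.0,  23,  29, 10, 0.2,  2, 150, 0.5, 0.2,   4, 30),
    tea             = c( 1, 200,  30, 1, 0.2, 0, 0, 0, 0, 0, 0, 0, 0,   0, 0, 0,   0, 0, 0.01, 0.0, 0.00,  5, 0, 0, 0, 0,   0,   1,  2, 0.0,  1,  20, 0.0, 0,   2, 0)
  )
  colnames(m) <- cols
  m <- as.data.frame(m)
  # column-level calibration so the simulated cohort's mean daily intakes
  # land at the magnitudes typical of Spanish FFQ totals in this age group
  cal <- c(kcal = 1.11, carb = 1.25, prot = 1.04, fat = 1.06, sfa = 0.98,
           trans = 0.54, linoleic = 1.27, chol_mg = 1.19, fibre = 0.94,
           alcohol = 1.07, vita_ug = 1.20, b1_mg = 1.30, b2_mg = 1.27,
           b3_mg = 1.35, b9_ug = 0.75, b12_ug = 1.10, c_mg = 0.85,
           e_mg = 0.61, ca_mg = 1.28, p_mg = 1.13, mg_mg = 1.19,
           fe_mg = 1.11, iodine_ug = 1.80, k_mg = 1.24, se_ug = 1.14,
           na_mg = 1.48, pufa = 1.12)
  for (nm in names(cal)) m[[nm]] <- m[[nm]] * cal[[nm]]
  m
}

#' Synthetic food-composition table for the 143-item FFQ
#'
#' @param templates Per-group density templates (per 100 g/ml), as from
#'   `food_group_templates()`; exposed so reference tables can be overridden.
#' @return Data frame, one row per item: `item_id`, `item`, `food_group`,
#'   `portion_g`, per-portion `energy_kcal` and nutrient contents, and `gi`.
#' @export
default_food_composition <- function(templates = food_group_templates()) {
  groups <- rownames(templates)
  rows <- lapply(seq_along(groups), function(g) {
    tpl <- templates[g, ]
    n <- tpl$n_items
    # deterministic within-group spread of portion sizes, +/-20%
    spread <- if (n == 1) 1 else seq(0.8, 1.2, length.out = n)
    portion <- round(tpl$portion_g * spread, 1)
    per100 <- unlist(tpl[!(names(tpl) %in%
                             c("n_items", "portion_g", "group_daily_g", "gi"))])
    per_portion <- outer(portion / 100, per100)
    colnames(per_portion) <- names(per100)
    data.frame(
      item = paste0(groups[g], "_", seq_len(n)),
      food_group = groups[g],
      portion_g = portion,
      per_portion,
      gi = rep(tpl$gi, n),
      stringsAsFactors = FALSE
    )
  })
  fct <- do.call(rbind, rows)
  rownames(fct) <- NULL
  fct$item_id <- seq_len(nrow(fct))
  # rename density columns to the intake-variable vocabulary
  ren <- c(
    kcal = "energy_kcal", carb = "carbohydrate_g", prot = "protein_g",
    fat = "fat_g", sfa = "sfa_g", mufa = "mufa_g", pufa = "pufa_g",
    trans = "trans_g", linoleic = "linoleic_g", omega3 = "omega3_g",
    chol_mg = "cholesterol_mg", fibre = "fibre_g", alcohol = "alcohol_g",
    vita_ug = "vitamin_a_ug", b1_mg = "vitamin_b1_mg", b2_mg = "vitamin_b2_mg",
    b3_mg = "vitamin_b3_mg", b6_mg = "vitamin_b6_mg", b9_ug = "vitamin_b9_ug",
    b12_ug = "vitamin_b12_ug", c_mg = "vitamin_c_mg", d_ug = "vitamin_d_ug",
    e_mg = "vitamin_e_mg", ca_mg = "calcium_mg", p_mg = "phosphorus_mg",
    mg_mg = "magnesium_mg", fe_mg = "iron_mg", iodine_ug = "iodine_ug",
    k_mg = "potassium_mg", se_ug = "selenium_ug", zn_mg = "zinc_mg",
    na_mg = "sodium_mg"
  )
  names(fct)[match(names(ren), names(fct))] <- ren
  fct[c("item_id", "item", "food_group", "portion_g", unname(ren), "gi")]
}

# typical daily grams consumed per food group (drives FFQ simulation)
default_group_daily_g <- function(templates = food_group_templates()) {
  stats::setNames(templates$group_daily_g, rownames(templates))
}
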
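test_that("frequency categories convert to servings/day at their midpoints", {
  expect_equal(frequency_to_per_day("never"), 0)
  expect_equal(frequency_to_per_day("5-6/week"), 5.5 / 7)
  expect_equal(frequency_to_per_day("2-4/week"), 3 / 7)
  expect_equal(frequency_to_per_day("1-3/month"), 2 / 30.4)
  expect_equal(frequency_to_per_day(">=6/day"), 6)
  expect_error(frequency_to_per_day("sometimes"), "unknown")
  # midpoint overrides
  expect_equal(frequency_to_per_day("1/day", midpoints = c("1/day" = 1.1)),
               1.1)
})

test_that("display formatting truncates, never rounds", {
  expect_equal(format_servings(5.5 / 7), "0.78")   # 0.7857 -> 0.78
  expect_equal(format_servings(0.999), "0.99")
  expect_equal(format_servings(0), "0.00")
})

test_that("nutrient profile is frequency times portion content, plus supplements", {
  fct <- toy_fct()
  resp <- data.frame(item_id = 1:2, category = c("1/day", "never"))
  prof <- compute_nutrient_profile(resp, fct)
  # hand oracle: one item eaten daily, 50 g portion with 10 g fat, 98 kcal
  expect_equal(prof$fat_g, 10)
  expect_equal(prof$energy_kcal, 98)
  expect_equal(prof$fat_pte, 100 * 90 / 98)
  expect_equal(prof$protein_pte, 100 * 8 / 98)
  # additivity of supplements
  prof2 <- compute_nutrient_profile(resp, fct,
                                    supplements = c(iodine_ug = 100))
  expect_equal(prof2$iodine_ug, 300)
  expect_error(compute_nutrient_profile(resp, fct,
                                        supplements = c(iodine_ug = -1)),
               "non-negative")
  # all never -> zero profile
  resp0 <- data.frame(item_id = 1:2, category = "never")
  prof0 <- compute_nutrient_profile(resp0, fct)
  expect_true(all(unlist(prof0) == 0))
  # unmapped item rejected with its id
  expect_error(
    compute_nutrient_profile(data.frame(item_id = 9, category = "never"), fct),
    "9")
})

test_that("profile is additive over items", {
  fct <- toy_fct()
  both <- compute_nutrient_profile(
    data.frame(item_id = 1:2, category = c("1/day", "2-3/day")), fct)
  only1 <- compute_nutrient_profile(
    data.frame(item_id = 1:2, category = c("1/day", "never")), fct)
  only2 <- compute_nutrient_profile(
    data.frame(item_id = 1:2, category = c("never", "2-3/day")), fct)
  for (nm in c("energy_kcal", "fat_g", "protein_g", "iodine_ug")) {
    expect_equal(both[[nm]], only1[[nm]] + only2[[nm]])
  }
})

test_that("extreme-energy rule uses sex-specific inclusive bounds", {
  expect_false(energy_exclusion(450, "female"))
  expect_true(energy_exclusion(500, "female"))
  expect_true(energy_exclusion(3500, "female"))
  expect_false(energy_exclusion(3501, "female"))
  expect_true(energy_exclusion(800, "male"))
  expect_false(energy_exclusion(799, "male"))
  expect_false(energy_exclusion(4001, "male"))
  expect_true(is.na(energy_exclusion(NA, "male")))
  # idempotent: filtering a filtered vector changes nothing
  e <- c(300, 900, 2500, 4200)
  keep <- energy_exclusion(e, rep("male", 4))
  expect_equal(energy_exclusion(e[keep], rep("male", sum(keep))),
               rep(TRUE, sum(keep)))
})

test_that("MD adherence counts met criteria, bounded 0-17", {
  full <- md17_full_intakes()
  expect_equal(score_md17(full), 17L)
  none <- full
  none[] <- c(0, 0, 0, 0, 999, 999, 999, 999, 0, 0, 999, 0, 0, 999, 999, 999)
  expect_equal(score_md17(none), 0L)
  # a profile meeting exactly five of the seventeen items
  crit <- md17_criteria_default()
  five <- none
  five[c("olive_oil", "vegetables", "fruits")] <- c(45, 300, 400)
  # olive oil satisfies items 1 and 2; vegetables and fruits one each -> 4
  expect_equal(score_md17(five), 4L)
  five["nuts"] <- 20
  expect_equal(score_md17(five), 5L)
  # permutation of the criteria rows leaves the score unchanged
  set.seed(1)
  expect_equal(score_md17(full, crit[sample(17), ]), 17L)
  # missing input propagates
  expect_true(is.na(score_md17(full[-1])))
  expect_error(score_md17(full, crit[1:10, ]), "17")
})

test_that("DII is zero at the global means and matches the two-parameter hand value", {
  params <- dii_parameters_default()
  at_means <- stats::setNames(params$global_mean, params$intake_variable)
  expect_equal(compute_dii(at_means, params), 0)
  # hand oracle: z = +1 and -1, c = +/-0.6827, effects +0.5/-0.4
  toy <- data.frame(parameter = c("a", "b"), intake_variable = c("a", "b"),
                    global_mean = c(10, 5), global_sd = c(2, 1),
                    effect_score = c(0.5, -0.4))
  val <- compute_dii(c(a = 12, b = 4), toy)
  expect_equal(val, 0.5 * (2 * pnorm(1) - 1) - 0.4 * (2 * pnorm(-1) - 1),
               tolerance = 1e-12)
  expect_equal(val, 0.6144, tolerance = 1e-4)
  expect_error(compute_dii(c(a = 12), toy), "b")
})

test_that("DII is bounded by the total effect mass and increasing in pro-inflammatory intakes", {
  params <- dii_parameters_default()
  bound <- sum(abs(params$effect_score))
  set.seed(42)
  for (i in 1:50) {
    intakes <- stats::setNames(
      params$global_mean * exp(rnorm(nrow(params), 0, 1)),
      params$intake_variable)
    expect_lt(abs(compute_dii(intakes, params)), bound)
  }
  # raising a positive-effect parameter raises the score
  base <- stats::setNames(params$global_mean, params$intake_variable)
  j <- which(params$parameter == "sfa")
  up <- base
  up[params$intake_variable[j]] <- base[params$intake_variable[j]] +
    params$global_sd[j]
  expect_gt(compute_dii(up, params), compute_dii(base, params))
  # translation property: adding k*sd moves the centred percentile by
  # 2*(Phi(z+k) - Phi(z))
  delta <- compute_dii(up, params) - compute_dii(base, params)
  expect_equal(delta, params$effect_score[j] * 2 * (pnorm(1) - pnorm(0)),
               tolerance = 1e-12)
})

test_that("empirical-percentile mode ranks against a supplied cohort", {
  toy <- data.frame(parameter = "a", intake_variable = "a",
                    global_mean = 10, global_sd = 2, effect_score = 1)
  ref <- data.frame(a = 1:100)
  val <- compute_dii(c(a = 50), toy, percentile = "empirical",
                     cohort_intakes = ref)
  expect_equal(val, 2 * 0.5 - 1)
  expect_error(compute_dii(c(a = 50), toy, percentile = "empirical"),
               "cohort_intakes")
})
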
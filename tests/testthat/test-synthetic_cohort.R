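test_that("spec validation rejects bad inputs with diagnostics", {
  expect_error(cohort_spec(-1), "non-negative")
  expect_error(cohort_spec(10, fraction_women = 1.2), "fraction_women")
  badR <- default_component_correlation()
  badR["sbp", "dbp"] <- badR["dbp", "sbp"] <- 0.999
  badR["sbp", "wc"] <- badR["wc", "sbp"] <- 0.9
  badR["dbp", "wc"] <- badR["wc", "dbp"] <- -0.9
  expect_error(cohort_spec(10, component_correlation = badR),
               "positive-definite")
  expect_error(cohort_spec(10, component_sds = c(wc = -1, tag = 1, hdl = 1,
                                                 sbp = 1, dbp = 1,
                                                 glucose = 1)),
               "positive")
})

test_that("edge cohorts: empty, and all-female with the female age window", {
  co0 <- generate_cohort(cohort_spec(0))
  expect_equal(nrow(co0$subjects), 0)
  co <- generate_cohort(cohort_spec(50, fraction_women = 1, seed = 4),
                        include_ffq = FALSE)
  expect_true(all(co$subjects$sex == "female"))
  expect_true(all(co$subjects$age >= 60 & co$subjects$age <= 75))
})

test_that("same spec and seed give a byte-identical cohort", {
  s <- cohort_spec(120, seed = 99)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$ffq, c2$ffq)
  expect_identical(c1$activity, c2$activity)
  c3 <- generate_cohort(cohort_spec(120, seed = 100))
  expect_false(identical(c1$subjects, c3$subjects))
})

test_that("every generated subject satisfies the eligibility constraints", {
  spec <- cohort_spec(500, seed = 8,
                      missing_rates = c(pa = 0, ffq = 0, risk_info = 0))
  co <- generate_cohort(spec, include_ffq = FALSE)
  s <- co$subjects
  expect_equal(nrow(s), 500)
  expect_true(all(s$bmi >= 27 & s$bmi < 40))
  men <- s$sex == "male"
  expect_true(all(s$age[men] >= 55 & s$age[men] <= 75))
  expect_true(all(s$age[!men] >= 60 & s$age[!men] <= 75))
  flags <- mets_component_flags(s)
  expect_true(all(flags$n_mets_criteria >= 3))
})

test_that("infeasible constraints fail after bounded attempts with a message", {
  spec <- cohort_spec(5, seed = 1, bmi_range = c(27, 40),
                      component_means_male = c(wc = 60, tag = 60, hdl = 90,
                                               sbp = 100, dbp = 60,
                                               glucose = 70),
                      component_means_female = c(wc = 60, tag = 60, hdl = 90,
                                                 sbp = 100, dbp = 60,
                                                 glucose = 70),
                      medication_logit = list(
                        antihypertensive = c(-20, 0), cholesterol = c(-20, 0),
                        insulin = c(-20, 0), oral_hypoglycaemic = c(-20, 0),
                        aspirin = c(-20, 0)),
                      max_attempts_per_subject = 50)
  expect_error(generate_cohort(spec, include_ffq = FALSE), "attempts")
})

test_that("FFQ layer answers all 143 items once per subject", {
  spec <- cohort_spec(40, seed = 12, missing_rates = c(pa = 0, ffq = 0,
                                                       risk_info = 0))
  co <- generate_cohort(spec)
  counts <- table(co$ffq$subject_id)
  expect_true(all(counts == 143))
  expect_true(all(co$ffq$category %in% names(ffq_frequency_levels())))
  # one response per item
  expect_false(any(duplicated(co$ffq[c("subject_id", "item_id")])))
})

test_that("configured food couplings shift group means in the stated direction", {
  spec <- cohort_spec(3000, seed = 13,
                      missing_rates = c(pa = 0, ffq = 0, risk_info = 0))
  co <- generate_cohort(spec)
  s <- score_cohort(co)
  lt <- s$latent_tertile
  # nuts lower, red/processed meat and spirits higher in the top tertile
  expect_lt(mean(s$nuts[lt == "T3"]), mean(s$nuts[lt == "T1"]))
  expect_gt(mean(s$processed_meat[lt == "T3"]),
            mean(s$processed_meat[lt == "T1"]))
  expect_gt(mean(s$other_oils[lt == "T3"]), mean(s$other_oils[lt == "T1"]))
  # and the activity/behaviour couplings point the printed way
  expect_lt(mean(s$ltpa_moderate[lt == "T3"]),
            mean(s$ltpa_moderate[lt == "T1"]))
  expect_gt(mean(s$bdi_score[lt == "T3"]), mean(s$bdi_score[lt == "T1"]))
  expect_lt(mean(s$chair_stand[lt == "T3"]), mean(s$chair_stand[lt == "T1"]))
})

test_that("with no coupling, severity-tertile tests of lifestyle are null-calibrated", {
  # Kruskal-Wallis p-values across seed replicates should be uniform
  nrep <- 200
  pvals <- numeric(nrep)
  spec <- null_spec(cohort_spec(3000, seed = 1))
  cfg <- metsss_config()
  for (r in seq_len(nrep)) {
    spec$seed <- r
    co <- generate_cohort(spec, include_ffq = FALSE)
    met <- compute_metsss(co$subjects, cfg)
    tert <- assign_tertiles(met)$tertile
    pvals[r] <- test_nonparametric(co$subjects$ltpa_total, tert)$p
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
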
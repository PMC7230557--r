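test_that("VAI equals 1 on the healthy reference manifold for both sexes", {
  expect_equal(compute_vai("male", wc = 39.68 + 1.88 * 30, bmi = 30,
                           tag = 1.03, hdl = 1.31, units = "mmol/l"), 1)
  expect_equal(compute_vai("female", wc = 36.58 + 1.89 * 28, bmi = 28,
                           tag = 0.81, hdl = 1.52, units = "mmol/l"), 1)
  # reference manifold across a BMI sweep
  for (bmi in c(22, 27, 33, 39)) {
    expect_equal(compute_vai("male", 39.68 + 1.88 * bmi, bmi, 1.03, 1.31,
                             units = "mmol/l"), 1)
  }
})

test_that("VAI matches the hand-evaluated worked example and is multiplicative", {
  # (100/97.06) * (1.5/0.81) * (1.52/1.2)
  v <- compute_vai("female", wc = 100, bmi = 32, tag = 1.5, hdl = 1.2,
                   units = "mmol/l")
  expect_equal(v, (100 / (36.58 + 1.89 * 32)) * (1.5 / 0.81) * (1.52 / 1.2))
  expect_equal(v, 2.417, tolerance = 5e-4)
  expect_equal(compute_vai("female", 100, 32, 3.0, 1.2, units = "mmol/l"),
               2 * v)
  # mg/dL inputs convert through the standard factors
  expect_equal(compute_vai("female", 100, 32, 1.5 * 88.57, 1.2 * 38.67), v)
  expect_error(compute_vai("male", 100, 30, -1, 1.2, units = "mmol/l"),
               "positive")
})

test_that("MetSSS is zero at thresholds and counts standardized exceedances", {
  cfg <- metsss_config()
  expect_equal(compute_metsss(panel_at_thresholds("male"), cfg), 0)
  expect_equal(compute_metsss(panel_at_thresholds("female"), cfg), 0)
  # one component one scale-unit above threshold -> score 1 under sum
  p <- panel_at_thresholds("male")
  p$glucose <- p$glucose + cfg$scales[["glucose"]]
  expect_equal(compute_metsss(p, cfg), 1)
  # HDL contributes when below threshold
  p2 <- panel_at_thresholds("male")
  p2$hdl <- p2$hdl - cfg$scales[["hdl"]]
  expect_equal(compute_metsss(p2, cfg), 1)
  # euclidean aggregation
  p3 <- panel_at_thresholds("male")
  p3$glucose <- p3$glucose + cfg$scales[["glucose"]]
  p3$sbp <- p3$sbp + cfg$scales[["sbp"]]
  cfg_e <- metsss_config(aggregation = "euclidean")
  expect_equal(compute_metsss(p3, cfg_e), sqrt(2))
  expect_equal(compute_metsss(p3, cfg), 2)
  # missing component -> missing score
  p4 <- panel_at_thresholds("male"); p4$wc <- NA
  expect_true(is.na(compute_metsss(p4, cfg)))
})

test_that("MetSSS is non-decreasing in every risk direction", {
  set.seed(11)
  cfg <- metsss_config()
  for (i in 1:30) {
    p <- panel_at_thresholds(sample(c("male", "female"), 1))
    p$wc <- p$wc + runif(1, -20, 20)
    p$glucose <- p$glucose + runif(1, -30, 60)
    p$tag <- p$tag + runif(1, -50, 150)
    base <- compute_metsss(p, cfg)
    up <- p
    comp <- sample(c("wc", "tag", "sbp", "dbp", "glucose"), 1)
    up[[comp]] <- up[[comp]] + runif(1, 0, 30)
    expect_gte(compute_metsss(up, cfg), base)
    dn <- p
    dn$hdl <- dn$hdl - runif(1, 0, 15)
    expect_gte(compute_metsss(dn, cfg), base)
  }
})

test_that("tertile assignment splits at inverse-ECDF thirds, inclusive left", {
  t <- assign_tertiles(1:9)
  expect_equal(t$cutpoints, c(3, 6))
  expect_equal(as.vector(table(t$tertile)), c(3, 3, 3))
  # permutation invariance
  set.seed(3)
  x <- rnorm(100)
  perm <- sample(100)
  expect_equal(assign_tertiles(x)$tertile[perm],
               assign_tertiles(x[perm])$tertile)
  # rank-based: monotone transform preserves membership
  expect_equal(assign_tertiles(x)$tertile, assign_tertiles(exp(x))$tertile)
  expect_error(assign_tertiles(rep(1, 10)), "identical")
  expect_error(assign_tertiles(c(1, 2)), ">= 3")
})

test_that("empirical cut-points converge to true distribution tertiles", {
  set.seed(2024)
  x <- rnorm(1e5, mean = 10, sd = 2)
  cp <- assign_tertiles(x)$cutpoints
  truth <- qnorm(c(1, 2) / 3, 10, 2)
  expect_lt(max(abs(cp - truth) / abs(truth)), 0.01)
})

test_that("Friedewald LDL reconstitutes total cholesterol and respects validity", {
  expect_equal(friedewald_ldl(200, 50, 150), 120)
  expect_equal(friedewald_ldl(60, 60, 0), 0)
  expect_true(is.na(friedewald_ldl(200, 50, 450)))
  set.seed(5)
  tc <- runif(20, 150, 260); hdl <- runif(20, 35, 70); tag <- runif(20, 60, 390)
  expect_equal(friedewald_ldl(tc, hdl, tag) + hdl + tag / 5, tc)
})

test_that("BDI-II total sums 21 items within 0-63", {
  expect_equal(bdi_total(rep(3, 21)), 63L)
  expect_equal(bdi_total(rep(0, 21)), 0L)
  expect_equal(bdi_total(rep(1, 21)), 21L)
  m <- rbind(rep(0, 21), rep(3, 21))
  expect_equal(bdi_total(m), c(0L, 63L))
  expect_error(bdi_total(rep(1, 20)), "21")
  expect_error(bdi_total(c(rep(0, 20), 4)), "0..3")
})

test_that("MetS component flags require strict exceedance or medication", {
  p <- panel_at_thresholds("male")
  p$med_antihypertensive <- FALSE
  f <- mets_component_flags(p)
  expect_false(any(unlist(f[1, 1:5])))
  expect_equal(f$n_mets_criteria, 0)
  # drug-treated counts as meeting the blood-pressure criterion
  p$med_antihypertensive <- TRUE
  expect_true(mets_component_flags(p)$high_bp)
  expect_false(mets_component_flags(p, medication_counts = FALSE)$high_bp)
  # obesity at the standard BMI cut-off
  p$bmi <- 30
  expect_true(mets_component_flags(p)$obesity)
  p$bmi <- 29.9
  expect_false(mets_component_flags(p)$obesity)
})
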
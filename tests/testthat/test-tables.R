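analysed_fixture <- function(n = 400, seed = 6) {
  spec <- cohort_spec(n, seed = seed,
                      missing_rates = c(pa = 0.02, ffq = 0.01,
                                        risk_info = 0.05))
  res <- analyse_cohort(score_cohort(generate_cohort(spec)))
  res
}

test_that("the full analysis produces five tables in the study layout", {
  res <- analysed_fixture()
  # rare categories (insulin use) trip the asymptotic chi-square warning at
  # this fixture size
  tabs <- suppressWarnings(build_tables(res$analysed))
  expect_named(tabs, paste0("table", 1:5))
  for (tb in tabs) {
    expect_true(all(c("variable", "T1", "T2", "T3", "p", "p_sex_age",
                      "p_full", "pairwise") %in% names(tb)))
  }
  # quantitative rows carry all three p-value columns
  expect_true(all(nchar(tabs$table2$p_full) > 0))
  # mean +/- SD | median (IQR) cell shape
  expect_match(tabs$table3$T1[1], "^[0-9.]+ ± [0-9.]+ \\| [0-9.]+ \\([0-9.]+\\)$")
  # pairwise letters only from {a, b, c}
  expect_true(all(grepl("^[abc,]*$", tabs$table2$pairwise)))
})

test_that("categorical table percentages sum to 100 within tertile", {
  res <- analysed_fixture()
  d <- describe_by_tertile(res$analysed$education, res$analysed$tertile)
  for (g in c("T1", "T2", "T3")) {
    expect_equal(sum(d$pct[d$tertile == g]), 100, tolerance = 1e-9)
  }
})

test_that("exclusion flow accounts for every generated subject", {
  res <- analysed_fixture()
  expect_equal(sum(res$flow$n_excluded) + res$n_final, res$n_initial)
  expect_equal(res$flow$stage,
               c("missing_pa", "pa_outlier", "extreme_energy", "missing_ffq",
                 "missing_risk_info"))
  # tertile groups are near-balanced
  expect_lt(diff(range(table(res$analysed$tertile))), 0.1 * res$n_final)
})

test_that("p-value formatting rounds to three decimals with a floor label", {
  expect_equal(metsev:::format_p(0.1234), "0.123")
  expect_equal(metsev:::format_p(0.0004), "<0.001")
  expect_equal(metsev:::format_p(NA), "")
})

test_that("tables write to delimited text and flow is preserved", {
  res <- analysed_fixture(200, seed = 14)
  # rare categories (insulin use) make the asymptotic chi-square warn at
  # this deliberately small fixture size
  tabs <- suppressWarnings(build_tables(res$analysed))
  dir <- withr::local_tempdir()
  write_outputs(tabs, res$flow, res$analysed, dir)
  expect_true(file.exists(file.path(dir, "table1.csv")))
  fl <- read.csv(file.path(dir, "exclusion_flow.csv"))
  expect_equal(fl$n_excluded, res$flow$n_excluded)
})
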
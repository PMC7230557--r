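test_that("MET-minutes multiply intensity, duration and frequency", {
  mm <- met_minutes(6, 30, 3)
  expect_equal(mm$weekly, 540)
  expect_equal(mm$daily, 540 / 7)
  expect_equal(met_minutes(6, 30, 0)$weekly, 0)
  # bilinear in duration and frequency
  expect_equal(met_minutes(6, 60, 3)$weekly, 2 * mm$weekly)
  expect_equal(met_minutes(6, 30, 6)$weekly, 2 * mm$weekly)
  expect_error(met_minutes(0, 30, 3), "positive")
  expect_error(met_minutes(6, 30, 8), "0, 7")
})

test_that("intensity classes honour printed limits and partition all MET values", {
  expect_equal(as.character(classify_intensity(3.9)), "light")
  expect_equal(as.character(classify_intensity(4.0)), "moderate")
  expect_equal(as.character(classify_intensity(5.7)), "moderate")
  expect_equal(as.character(classify_intensity(6.0)), "vigorous")
  # every positive MET maps to exactly one class
  grid <- seq(0.1, 15, by = 0.1)
  cls <- classify_intensity(grid)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), length(grid))
})

test_that("PA outlier filter excludes at 3 or more stratum SDs, single pass", {
  # one gross outlier among 49 identical-ish values: z about 6.9
  x <- c(rep(100, 49), 10000)
  sex <- rep("male", 50)
  age <- rep(60, 50)
  keep <- pa_outlier_filter(x, sex, age)
  expect_equal(which(!keep), 50L)
  # constant stratum: SD 0, nobody excluded
  expect_true(all(pa_outlier_filter(rep(5, 10), rep("female", 10),
                                    rep(65, 10))))
  # boundary: exactly mean + 3 SD is excluded ("3 or more"); solve for the
  # value whose z-score within its own stratum is exactly 3
  # a point's z within its own sample of size n is bounded by (n-1)/sqrt(n),
  # so the stratum needs >= 11 members for z = 3 to be reachable
  base <- seq(-2, 2, length.out = 11)
  zscore <- function(t) {
    v <- c(base, t)
    (t - mean(v)) / sd(v) - 3
  }
  t_star <- uniroot(zscore, c(3, 500), tol = 1e-12)$root
  nn <- length(base) + 1
  keep_at <- pa_outlier_filter(c(base, t_star), rep("male", nn), rep(60, nn))
  keep_below <- pa_outlier_filter(c(base, t_star - 0.05), rep("male", nn),
                                  rep(60, nn))
  expect_false(keep_at[nn])
  expect_true(keep_below[nn])
  # order invariance
  set.seed(9)
  xx <- rnorm(200, 500, 100); xx[7] <- 5000
  sx <- rep(c("male", "female"), 100); ag <- runif(200, 55, 74)
  perm <- sample(200)
  expect_equal(pa_outlier_filter(xx, sx, ag)[perm],
               pa_outlier_filter(xx[perm], sx[perm], ag[perm]))
})

test_that("sedentary categories map through the declared 12-point convention", {
  expect_equal(sedentary_hours(1), 0)
  expect_equal(sedentary_hours(12), 9)
  expect_equal(sedentary_hours(c(2, 5)), c(0.5, 2))
  expect_error(sedentary_hours(13), "range")
  expect_error(sedentary_hours(0), "range")
  expect_error(sedentary_hours(1, mapping = 1:5), "12")
})

test_that("sleep averages weekdays and weekends 5:2", {
  expect_equal(sleep_average(7, 8), 51 / 7)
  expect_equal(round(sleep_average(7, 8), 2), 7.29)
  expect_error(sleep_average(-1, 8), ">= 0")
})

test_that("LTPA summary sums records by intensity and conserves the total", {
  recs <- data.frame(
    subject_id = c(1, 1, 2),
    met_score = c(3.3, 6.0, 4.5),
    minutes_per_day = c(30, 30, 60),
    days_per_week = c(7, 3, 2)
  )
  s <- summarize_ltpa(recs, subject_ids = 1:3)
  expect_equal(s$ltpa_light[1], 3.3 * 30 * 7 / 7)
  expect_equal(s$ltpa_vigorous[1], 6 * 30 * 3 / 7)
  expect_equal(s$ltpa_moderate[2], 4.5 * 60 * 2 / 7)
  expect_equal(s$ltpa_total, s$ltpa_light + s$ltpa_moderate + s$ltpa_vigorous)
  expect_equal(s$ltpa_total[3], 0)
})
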
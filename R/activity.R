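#' MET-minutes of an activity record
#'
#' Energy expenditure of a leisure-time activity as MET-minutes: intensity
#' (MET score from the physical-activity compendium) multiplied by duration.
#' Weekly MET-min = MET x min/day x days/week; daily = weekly / 7.
#'
#' @param met_score Positive MET intensity.
#' @param minutes_per_day Minutes per session day (>= 0).
#' @param days_per_week Days per week (0..7).
#' @return List with `weekly` and `daily` MET-minutes (vectorized).
#' @examples
#' met_minutes(6, 30, 3)  # 540 MET-min/week
#' @export
met_minutes <- function(met_score, minutes_per_day, days_per_week) {
  if (any(met_score <= 0)) stop("met_score must be positive", call. = FALSE)
  if (any(minutes_per_day < 0)) stop("minutes_per_day must be >= 0", call. = FALSE)
  if (any(days_per_week < 0 | days_per_week > 7)) {
    stop("days_per_week must be in [0, 7]", call. = FALSE)
  }
  weekly <- met_score * minutes_per_day * days_per_week
  list(weekly = weekly, daily = weekly / 7)
}

#' Classify activity intensity from its MET score
#'
#' Light below 4.0 MET, vigorous at or above 6.0 MET, moderate in between.
#' The printed class limits (4-5.5 for moderate) leave (5.5, 6.0) unassigned;
#' moderate is implemented as the interval [4.0, 6.0) so the three classes
#' partition all positive intensities.
#'
#' @param met_score Positive MET score (vectorized).
#' @return Factor with levels light, moderate, vigorous.
#' @export
classify_intensity <- function(met_score) {
  if (any(met_score <= 0)) stop("met_score must be positive", call. = FALSE)
  cls <- ifelse(met_score < 4, "light",
                ifelse(met_score >= 6, "vigorous", "moderate"))
  factor(cls, levels = c("light", "moderate", "vigorous"))
}

#' Physical-activity outlier filter
#'
#' Flags subjects whose total weekly MET-minutes lie 3 or more standard
#' deviations from the mean of their sex x age-band stratum. Stratum means
#' and SDs are computed once on the pre-filter data (single pass, no
#' re-iteration). Degenerate strata (SD = 0) exclude nobody.
#'
#' @param total_weekly Numeric vector of total MET-min/week per subject.
#' @param sex Character vector (`"male"`/`"female"`).
#' @param age Numeric ages in years.
#' @param age_breaks Band boundaries; default 5-year bands 55-59, 60-64,
#'   65-69, 70-75.
#' @param k SD multiple, default 3.
#' @return Logical vector: `TRUE` = keep. `NA` inputs return `NA`.
#' @export
pa_outlier_filter <- function(total_weekly, sex, age,
                              age_breaks = c(55, 60, 65, 70, 76), k = 3) {
  band <- cut(age, breaks = age_breaks, right = FALSE, include.lowest = TRUE)
  stratum <- interaction(sex, band, drop = TRUE)
  mu <- tapply(total_weekly, stratum, mean, na.rm = TRUE)
  sdev <- tapply(total_weekly, stratum, stats::sd, na.rm = TRUE)
  z <- abs(total_weekly - mu[stratum]) / sdev[stratum]
  keep <- ifelse(is.na(sdev[stratum]) | sdev[stratum] == 0, TRUE, z < k)
  unname(ifelse(is.na(total_weekly), NA, keep))
}

#' Default sitting-time category mapping
#'
#' The sedentary-behaviour questionnaire records each behaviour in 12 ordered
#' categories spanning 0 to >= 9 h/day. The exact category boundaries are a
#' declared convention: half-hour steps up to 2 h, hourly after, with the
#' open-ended top category mapped to its lower bound of 9 h.
#'
#' @return Numeric vector of length 12: hours/day per category index.
#' @export
sedentary_category_hours <- function() {
  c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9)
}

#' Hours/day of a sedentary behaviour from its category index
#'
#' @param category Integer vector of category indices in 1..12.
#' @param mapping Category-to-hours mapping covering 12 categories.
#' @return Numeric hours/day.
#' @export
sedentary_hours <- function(category, mapping = sedentary_category_hours()) {
  if (length(mapping) != 12) {
    stop("sedentary mapping must cover 12 categories", call. = FALSE)
  }
  ok <- is.na(category) | (category >= 1 & category <= 12 &
                             category == floor(category))
  if (!all(ok)) stop("sedentary category out of range 1..12", call. = FALSE)
  mapping[category]
}

#' Average daily sleep from weekday and weekend reports
#'
#' Weighted mean: (5 x weekday + 2 x weekend) / 7.
#'
#' @param weekday,weekend Hours/day (>= 0).
#' @return Numeric hours/day.
#' @export
sleep_average <- function(weekday, weekend) {
  if (any(weekday < 0 | weekend < 0, na.rm = TRUE)) {
    stop("sleep hours must be >= 0", call. = FALSE)
  }
  (5 * weekday + 2 * weekend) / 7
}

#' Summarize leisure-time physical activity per subject
#'
#' Aggregates long-format activity records (one row per subject x activity)
#' into daily MET-minutes by intensity class. Total = light + moderate +
#' vigorous by construction.
#'
#' @param records Data frame with columns `subject_id`, `met_score`,
#'   `minutes_per_day`, `days_per_week`.
#' @param subject_ids Ids to report (subjects with no records get 0).
#' @return Data frame: `subject_id`, `ltpa_light`, `ltpa_moderate`,
#'   `ltpa_vigorous`, `ltpa_total` (MET-min/day), `ltpa_weekly_total`.
#' @export
summarize_ltpa <- function(records, subject_ids = unique(records$subject_id)) {
  out <- data.frame(subject_id = subject_ids,
                    ltpa_light = 0, ltpa_moderate = 0, ltpa_vigorous = 0)
  if (nrow(records) > 0) {
    mm <- met_minutes(records$met_score, records$minutes_per_day,
                      records$days_per_week)
    cls <- classify_intensity(records$met_score)
    for (lev in levels(cls)) {
      sums <- tapply(mm$daily[cls == lev], records$subject_id[cls == lev],
                     sum, default = 0)
      col <- paste0("ltpa_", lev)
      idx <- match(names(sums), out$subject_id)
      out[[col]][idx[!is.na(idx)]] <- unname(sums)[!is.na(idx)]
    }
  }
  out$ltpa_total <- out$ltpa_light + out$ltpa_moderate + out$ltpa_vigorous
  out$ltpa_weekly_total <- out$ltpa_total * 7
  out
}
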
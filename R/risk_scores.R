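#' Visceral adiposity index
#'
#' Sex-specific product of an anthropometric ratio and two lipid ratios,
#' calibrated so that VAI = 1 for a healthy non-obese reference subject with
#' normal adipose distribution and normal lipids:
#'
#' men:   VAI = (WC / (39.68 + 1.88 BMI)) x (TAG / 1.03) x (1.31 / HDL)
#' women: VAI = (WC / (36.58 + 1.89 BMI)) x (TAG / 0.81) x (1.52 / HDL)
#'
#' The reference constants are lipid concentrations in mmol/L, so mg/dL
#' inputs are converted first (TAG / 88.57, HDL-c / 38.67).
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param tag Fasting triglycerides.
#' @param hdl HDL cholesterol.
#' @param units Units of `tag`/`hdl`: `"mg/dl"` (default) or `"mmol/l"`.
#' @return Numeric VAI (dimensionless).
#' @examples
#' compute_vai("male", wc = 39.68 + 1.88 * 30, bmi = 30,
#'             tag = 1.03, hdl = 1.31, units = "mmol/l")  # 1
#' @export
compute_vai <- function(sex, wc, bmi, tag, hdl, units = c("mg/dl", "mmol/l")) {
  units <- match.arg(units)
  sex <- match.arg_vec(sex, c("male", "female"))
  if (any(tag <= 0 | hdl <= 0, na.rm = TRUE)) {
    stop("TAG and HDL must be positive", call. = FALSE)
  }
  if (any(wc <= 0 | bmi <= 0, na.rm = TRUE)) {
    stop("WC and BMI must be positive", call. = FALSE)
  }
  if (units == "mg/dl") {
    tag <- tag / 88.57
    hdl <- hdl / 38.67
  }
  male <- sex == "male"
  denom <- ifelse(male, 39.68 + 1.88 * bmi, 36.58 + 1.89 * bmi)
  tag_ref <- ifelse(male, 1.03, 0.81)
  hdl_ref <- ifelse(male, 1.31, 1.52)
  (wc / denom) * (tag / tag_ref) * (hdl_ref / hdl)
}

#' Configuration for the metabolic syndrome severity score
#'
#' Six components: waist circumference, triglycerides, HDL cholesterol,
#' systolic and diastolic blood pressure, fasting glucose. Each has a
#' clinical threshold (sex-specific where the harmonized definition is),
#' a positive scale, and a risk direction (+1, except HDL where lower is
#' worse). Default thresholds are the harmonized joint-society values
#' (WC 102/88 cm men/women, TAG 150 mg/dL, HDL 40/50 mg/dL men/women,
#' BP 130/85 mmHg, glucose 100 mg/dL); default scales are reference
#' within-component SDs so exceedances are comparable across components.
#'
#' @param thresholds_male,thresholds_female Named numeric vectors over
#'   `wc`, `tag`, `hdl`, `sbp`, `dbp`, `glucose`.
#' @param scales Named positive numeric vector, same components.
#' @param aggregation `"sum"` (default) or `"euclidean"`.
#' @return Object of class `metsss_config`.
#' @export
metsss_config <- function(
    thresholds_male = c(wc = 102, tag = 150, hdl = 40, sbp = 130, dbp = 85,
                        glucose = 100),
    thresholds_female = c(wc = 88, tag = 150, hdl = 50, sbp = 130, dbp = 85,
                          glucose = 100),
    scales = c(wc = 10, tag = 60, hdl = 12, sbp = 15, dbp = 10, glucose = 25),
    aggregation = c("sum", "euclidean")) {
  comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
  aggregation <- match.arg(aggregation)
  for (v in list(thresholds_male, thresholds_female, scales)) {
    if (!setequal(names(v), comp)) {
      stop("config must name exactly the six components: ",
           paste(comp, collapse = ", "), call. = FALSE)
    }
  }
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  structure(list(thresholds_male = thresholds_male[comp],
                 thresholds_female = thresholds_female[comp],
                 scales = scales[comp],
                 directions = c(wc = 1, tag = 1, hdl = -1, sbp = 1, dbp = 1,
                                glucose = 1),
                 aggregation = aggregation),
            class = "metsss_config")
}

#' Metabolic syndrome severity score
#'
#' For each component the standardized exceedance beyond its clinical
#' threshold in the risk direction, truncated at zero:
#' h_i = max(0, d_i (x_i - t_i) / s_i), with d = -1 for HDL (so HDL below
#' threshold contributes). The score is the sum of the h_i (default) or
#' their Euclidean norm. A score of zero means every risk factor is at or
#' below its clinical threshold; the score is non-decreasing in every
#' risk-increasing component.
#'
#' @param panel Data frame with columns `sex`, `wc`, `tag`, `hdl`, `sbp`,
#'   `dbp`, `glucose` (lipids/glucose in mg/dL, BP in mmHg, WC in cm).
#' @param config A [metsss_config()].
#' @return Numeric score >= 0 per row; `NA` when any component is missing
#'   (such subjects are excluded downstream as lacking complete
#'   cardiovascular-risk information).
#' @export
compute_metsss <- function(panel, config = metsss_config()) {
  comp <- names(config$scales)
  missing_cols <- setdiff(c("sex", comp), names(panel))
  if (length(missing_cols) > 0) {
    stop("panel lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(panel[comp])
  n <- nrow(panel)
  thr <- matrix(rep(config$thresholds_female, each = n), n, 6)
  male <- panel$sex == "male"
  if (any(male)) {
    thr[male, ] <- matrix(rep(config$thresholds_male, each = sum(male)),
                          sum(male), 6)
  }
  d <- matrix(config$directions, n, 6, byrow = TRUE)
  s <- matrix(config$scales, n, 6, byrow = TRUE)
  h <- pmax(d * (x - thr) / s, 0)
  if (config$aggregation == "sum") rowSums(h) else sqrt(rowSums(h^2))
}

#' Tertile assignment with cut-points
#'
#' Splits scores at the empirical 1/3 and 2/3 quantiles (inverse-ECDF
#' quantiles, `type = 1`), inclusive on the left: T1 = score <= q1,
#' T2 = (q1, q2], T3 = > q2. Rank-based, so any strictly monotone transform
#' of the scores yields the same assignment.
#'
#' @param scores Numeric vector (NAs allowed; assigned `NA`).
#' @return List: `tertile` (factor T1/T2/T3) and `cutpoints` (length 2).
#' @export
assign_tertiles <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 3) stop("need >= 3 non-missing scores", call. = FALSE)
  if (length(unique(scores[ok])) == 1) {
    stop("tertiles undefined: all scores identical", call. = FALSE)
  }
  q <- stats::quantile(scores[ok], c(1, 2) / 3, type = 1, names = FALSE)
  tert <- rep(NA_character_, length(scores))
  tert[ok] <- ifelse(scores[ok] <= q[1], "T1",
                     ifelse(scores[ok] <= q[2], "T2", "T3"))
  list(tertile = factor(tert, levels = c("T1", "T2", "T3")),
       cutpoints = q)
}

#' Friedewald LDL cholesterol
#'
#' LDL = total cholesterol - HDL - TAG/5, all in mg/dL. The formula is not
#' valid at TAG >= 400 mg/dL; those values return `NA`.
#'
#' @param tc,hdl,tag Total cholesterol, HDL cholesterol and triglycerides
#'   in mg/dL.
#' @return LDL cholesterol, mg/dL.
#' @export
friedewald_ldl <- function(tc, hdl, tag) {
  ldl <- tc - hdl - tag / 5
  ldl[!is.na(tag) & tag >= 400] <- NA_real_
  ldl
}

#' Beck Depression Inventory-II total score
#'
#' Sum of the 21 item scores, each 0-3; totals range 0-63.
#'
#' @param items Numeric vector of length 21, or a matrix/data frame with 21
#'   columns (one row per subject).
#' @return Integer total(s) in 0..63.
#' @export
bdi_total <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1) else as.matrix(items)
  if (ncol(m) != 21) stop("BDI-II requires 21 item scores", call. = FALSE)
  if (any(m < 0 | m > 3 | m != floor(m), na.rm = TRUE)) {
    stop("BDI-II items must be integers in 0..3", call. = FALSE)
  }
  totals <- as.integer(rowSums(m))
  if (is.null(dim(items))) totals[1] else totals
}

#' Metabolic syndrome component flags and obesity
#'
#' One flag per harmonized component: true when the measurement strictly
#' exceeds its threshold in the risk direction (HDL strictly below), or when
#' the corresponding drug treatment is reported (drug-treated counts as
#' meeting the criterion). Obesity = BMI >= 30 kg/m^2.
#'
#' @param panel Data frame with `sex`, `wc`, `tag`, `hdl`, `sbp`, `dbp`,
#'   `glucose`, `bmi` and logical medication columns `med_antihypertensive`,
#'   `med_cholesterol`, `med_insulin`, `med_oral_hypoglycaemic` (missing
#'   medication columns are treated as all-false).
#' @param config A [metsss_config()] supplying thresholds.
#' @param medication_counts Logical; if `FALSE`, flags reflect measurements
#'   only.
#' @return Data frame of logicals: `high_bp`, `hyperglycaemia`,
#'   `hypertriglyceridemia`, `low_hdl`, `abdominal_obesity`, `obesity`,
#'   plus `n_mets_criteria` (count over the five components).
#' @export
mets_component_flags <- function(panel, config = metsss_config(),
                                 medication_counts = TRUE) {
  thr <- function(comp) {
    ifelse(panel$sex == "male", config$thresholds_male[comp],
           config$thresholds_female[comp])
  }
  med <- function(col) {
    if (medication_counts && col %in% names(panel)) {
      panel[[col]] %in% TRUE
    } else {
      rep(FALSE, nrow(panel))
    }
  }
  out <- data.frame(
    high_bp = (panel$sbp > thr("sbp") | panel$dbp > thr("dbp")) |
      med("med_antihypertensive"),
    hyperglycaemia = (panel$glucose > thr("glucose")) |
      med("med_insulin") | med("med_oral_hypoglycaemic"),
    hypertriglyceridemia = panel$tag > thr("tag"),
    low_hdl = panel$hdl < thr("hdl"),
    abdominal_obesity = panel$wc > thr("wc"),
    obesity = panel$bmi >= 30
  )
  out$n_mets_criteria <- rowSums(out[c("high_bp", "hyperglycaemia",
                                       "hypertriglyceridemia", "low_hdl",
                                       "abdominal_obesity")])
  out
}
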
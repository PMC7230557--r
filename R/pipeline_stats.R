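#' Apply an ordered exclusion cascade with flow accounting
#'
#' Subjects are evaluated stage by stage; a subject is excluded at the first
#' stage whose predicate fires and is never counted again. The flow report
#' conserves counts: initial n = sum of per-stage exclusions + final n.
#'
#' @param subjects Data frame, one row per subject.
#' @param stages Named list of predicate functions; each takes the subject
#'   data frame *restricted to subjects still in play* and returns a logical
#'   vector (`TRUE` = exclude at this stage; `NA` treated as not excluded).
#' @return List: `subjects` (retained rows), `flow` (data frame with
#'   `stage`, `n_excluded`), `n_initial`, `n_final`.
#' @export
apply_exclusions <- function(subjects, stages) {
  n_initial <- nrow(subjects)
  flow <- data.frame(stage = names(stages),
                     n_excluded = integer(length(stages)),
                     stringsAsFactors = FALSE)
  keep <- subjects
  for (i in seq_along(stages)) {
    if (nrow(keep) == 0) break
    drop <- stages[[i]](keep) %in% TRUE
    flow$n_excluded[i] <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }
  stopifnot(sum(flow$n_excluded) + nrow(keep) == n_initial)
  list(subjects = keep, flow = flow, n_initial = n_initial,
       n_final = nrow(keep))
}

#' Exclusion-flow arithmetic
#'
#' Pure accounting over a recruitment flow chart: final analysed n from an
#' initial count and ordered per-stage exclusion counts.
#'
#' @param n_initial Recruited count.
#' @param excluded Named integer vector of per-stage exclusions.
#' @return List: `flow` data frame, `n_initial`, `n_final`.
#' @export
exclusion_flow <- function(n_initial, excluded) {
  if (any(excluded < 0)) stop("exclusion counts must be >= 0", call. = FALSE)
  if (sum(excluded) > n_initial) {
    stop("exclusions exceed the initial count", call. = FALSE)
  }
  list(flow = data.frame(stage = names(excluded),
                         n_excluded = as.integer(excluded),
                         stringsAsFactors = FALSE),
       n_initial = as.integer(n_initial),
       n_final = as.integer(n_initial - sum(excluded)))
}

#' Default exclusion stages for a scored cohort
#'
#' The study cascade, in order: missing physical-activity questionnaires;
#' total-PA outliers (3 or more SD from the sex x age-band stratum mean,
#' strata computed once on the subjects entering that stage); extreme energy
#' intake (sex-specific); missing FFQ; incomplete cardiovascular-risk
#' information (any metabolic component missing).
#'
#' @return Named list of stage predicates for [apply_exclusions()], expecting
#'   columns `pa_missing`, `ltpa_weekly_total`, `sex`, `age`, `energy_kcal`,
#'   `ffq_missing`, and the six metabolic components.
#' @export
default_exclusion_stages <- function() {
  list(
    missing_pa = function(d) d$pa_missing %in% TRUE,
    pa_outlier = function(d) {
      !pa_outlier_filter(d$ltpa_weekly_total, d$sex, d$age)
    },
    extreme_energy = function(d) {
      energy_exclusion(d$energy_kcal, d$sex) %in% FALSE
    },
    missing_ffq = function(d) d$ffq_missing %in% TRUE | is.na(d$energy_kcal),
    missing_risk_info = function(d) {
      comp <- c("wc", "tag", "hdl", "sbp", "dbp", "glucose")
      rowSums(is.na(d[comp])) > 0
    }
  )
}

#' Per-tertile descriptive statistics
#'
#' Quantitative variables: n, mean, sample SD, median, IQR (Q3 - Q1 with
#' linear-interpolation quartiles, R type 7). Categorical variables: n and
#' column percentage per level within tertile.
#'
#' @param x Numeric vector, or factor/character for categoricals.
#' @param tertile Factor of tertile assignments (T1/T2/T3).
#' @return Data frame, one row per tertile (x level combination for
#'   categoricals).
#' @export
describe_by_tertile <- function(x, tertile) {
  tertile <- droplevels(as.factor(tertile))
  if (is.numeric(x)) {
    out <- do.call(rbind, lapply(levels(tertile), function(g) {
      v <- x[tertile == g & !is.na(x)]
      data.frame(tertile = g, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 median = stats::median(v),
                 iqr = unname(diff(stats::quantile(v, c(.25, .75), type = 7))))
    }))
  } else {
    x <- as.factor(x)
    tab <- table(x, tertile)
    pct <- prop.table(tab, margin = 2) * 100
    out <- data.frame(
      tertile = rep(colnames(tab), each = nrow(tab)),
      level = rep(rownames(tab), ncol(tab)),
      n = as.vector(tab),
      pct = as.vector(pct)
    )
  }
  rownames(out) <- NULL
  out
}

#' Chi-square test of a categorical variable across tertiles
#'
#' Pearson chi-square (no continuity correction) on the K x 3 contingency
#' table; rows with zero margin are dropped with a warning.
#'
#' @param x Factor/character variable.
#' @param tertile Tertile factor.
#' @return List: `statistic`, `df`, `p`.
#' @export
test_categorical <- function(x, tertile) {
  tab <- table(x, tertile)
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning("dropping zero-margin levels: ",
            paste(rownames(tab)[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' ANOVA / covariate-adjusted comparison of means across tertiles
#'
#' With no covariates this is the one-way ANOVA F-test. With covariates the
#' tertile factor is tested with a 2-df F-test in a linear model that
#' additively adjusts for them (dummy-coded categoricals), the standard
#' reading of ANCOVA. Pairwise tertile contrasts come from the same fitted
#' model (coefficient differences at common covariate values); their p-values
#' are Bonferroni-multiplied by 3 and capped at 1, and flagged when < 0.05.
#'
#' @param data Data frame holding the variable, tertile and covariates.
#' @param var Name of the response column.
#' @param tertile_col Name of the tertile factor column.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return List: `p` (tertile F-test), `F`, `df`, `pairwise` (data frame with
#'   `pair`, `estimate`, `p_raw`, `p_bonferroni`, `flag`), `n`, `fit`.
#' @export
test_quantitative <- function(data, var, tertile_col = "tertile",
                              covariates = character(0)) {
  use <- stats::complete.cases(data[c(var, tertile_col, covariates)])
  d <- data[use, , drop = FALSE]
  d[[tertile_col]] <- droplevels(as.factor(d[[tertile_col]]))
  rhs <- paste(c(tertile_col, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(var, "~", rhs)), data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit0 <- stats::update(fit, stats::as.formula(paste(". ~ . -", tertile_col)))
  a <- stats::anova(fit0, fit)
  Fval <- a$F[2]
  p <- a$`Pr(>F)`[2]

  # pairwise contrasts of tertile level effects from the fitted model
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  levs <- levels(d[[tertile_col]])
  coef_names <- paste0(tertile_col, levs[-1])
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    k <- stats::setNames(numeric(length(cf)), names(cf))
    if (pr[1] != levs[1]) k[paste0(tertile_col, pr[1])] <- -1
    if (pr[2] != levs[1]) k[paste0(tertile_col, pr[2])] <- 1
    est <- sum(k * cf)
    se <- sqrt(drop(t(k) %*% V %*% k))
    tval <- est / se
    praw <- 2 * stats::pt(abs(tval), df = fit$df.residual, lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = " vs "), estimate = est,
               p_raw = praw, p_bonferroni = min(1, 3 * praw),
               stringsAsFactors = FALSE)
  }))
  pw$flag <- pw$p_bonferroni < 0.05
  rownames(pw) <- NULL
  list(p = p, F = Fval, df = c(a$Df[2], fit$df.residual), pairwise = pw,
       n = nrow(d), fit = fit)
}

#' Kruskal-Wallis comparison across tertiles
#'
#' Tie-corrected Kruskal-Wallis rank test; pairwise comparisons run the same
#' test on each tertile pair with p-values Bonferroni-multiplied by 3.
#'
#' @param x Numeric vector.
#' @param tertile Tertile factor.
#' @return List: `statistic` (H), `df`, `p`, `pairwise` data frame.
#' @export
test_nonparametric <- function(x, tertile) {
  tertile <- droplevels(as.factor(tertile))
  ok <- !is.na(x) & !is.na(tertile)
  x <- x[ok]; tertile <- droplevels(tertile[ok])
  if (length(unique(x)) == 1) {
    levs <- levels(tertile)
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    pw <- data.frame(pair = vapply(pairs, paste, "", collapse = " vs "),
                     p_raw = 1, p_bonferroni = 1, flag = FALSE)
    return(list(statistic = 0, df = length(levs) - 1, p = 1, pairwise = pw))
  }
  kt <- stats::kruskal.test(x, tertile)
  levs <- levels(tertile)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- tertile %in% pr
    praw <- if (length(unique(x[sel])) == 1) 1 else
      stats::kruskal.test(x[sel], droplevels(tertile[sel]))$p.value
    data.frame(pair = paste(pr, collapse = " vs "), p_raw = praw,
               p_bonferroni = min(1, 3 * praw), stringsAsFactors = FALSE)
  }))
  pw$flag <- pw$p_bonferroni < 0.05
  rownames(pw) <- NULL
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, pairwise = pw)
}

#' Normality and homogeneity-of-variance checks
#'
#' Normality by a Kolmogorov-Smirnov test against a normal distribution with
#' the sample's own mean and SD (Lilliefors correction for the estimated
#' parameters); equality of variances across tertiles by Levene's test on
#' absolute deviations from the group means.
#'
#' @param x Numeric vector.
#' @param tertile Tertile factor (needed for Levene only).
#' @return List: `ks_p`, `levene_p` (`NA` with a warning on constant data).
#' @export
normality_and_variance_checks <- function(x, tertile = NULL) {
  x_ok <- x[!is.na(x)]
  if (length(unique(x_ok)) < 2) {
    warning("constant data: normality/variance tests undefined")
    return(list(ks_p = NA_real_, levene_p = NA_real_))
  }
  ks_p <- nortest::lillie.test(x_ok)$p.value
  levene_p <- NA_real_
  if (!is.null(tertile)) {
    ok <- !is.na(x) & !is.na(tertile)
    lt <- car::leveneTest(x[ok], droplevels(as.factor(tertile[ok])),
                          center = mean)
    levene_p <- lt$`Pr(>F)`[1]
  }
  list(ks_p = ks_p, levene_p = levene_p)
}
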
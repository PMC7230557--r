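# Delimited-text persistence for cohorts, reference tables and results.
# Canonical internal units: mg/dL for lipids and glucose, cm, kg, mmHg,
# MET-min/day; mmol/L inputs are converted on load and the conversion logged.

#' Lipid/glucose unit conversion to mg/dL
#'
#' @param x Numeric values.
#' @param analyte One of `"cholesterol"` (TC/HDL/LDL, factor 38.67),
#'   `"triglycerides"` (88.57), `"glucose"` (18.016).
#' @param from `"mmol/l"` or `"mg/dl"` (identity).
#' @return Values in mg/dL.
#' @export
to_mgdl <- function(x, analyte = c("cholesterol", "triglycerides", "glucose"),
                    from = c("mmol/l", "mg/dl")) {
  analyte <- match.arg(analyte)
  from <- match.arg(from)
  if (from == "mg/dl") return(x)
  factor <- c(cholesterol = 38.67, triglycerides = 88.57,
              glucose = 18.016)[[analyte]]
  message("converting ", analyte, " from mmol/L to mg/dL (x", factor, ")")
  x * factor
}

#' Write a cohort to a directory of delimited text files
#'
#' One wide subject table plus long-format companions keyed by `subject_id`,
#' and the generating spec as YAML. Output is deterministic: re-running with
#' the same cohort reproduces byte-identical files.
#'
#' @param cohort A `metsev_cohort`.
#' @param dir Output directory (created if needed).
#' @param sep Field separator, comma by default.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".csv")), sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  wr(cohort$subjects, "subjects")
  wr(cohort$activity, "activity")
  wr(cohort$sedentary, "sedentary")
  wr(cohort$bdi, "bdi")
  if (!is.null(cohort$ffq)) wr(cohort$ffq, "ffq")
  spec <- cohort$spec
  spec$component_correlation <- apply(spec$component_correlation, 1, as.list)
  yaml::write_yaml(lapply(unclass(spec), function(x) {
    if (is.factor(x)) as.character(x) else x
  }), file.path(dir, "spec.yaml"))
  invisible(dir)
}

cohort_schema <- function() {
  list(
    subjects = c("subject_id", "sex", "age", "bmi", "wc", "tag", "hdl",
                 "sbp", "dbp", "glucose"),
    activity = c("subject_id", "met_score", "minutes_per_day",
                 "days_per_week"),
    sedentary = c("subject_id", "cat_tv", "cat_total_sitting",
                  "sleep_weekday", "sleep_weekend"),
    bdi = c("subject_id", paste0("bdi_", 1:21)),
    ffq = c("subject_id", "item_id", "category")
  )
}

#' Load a cohort from a directory, with schema validation
#'
#' Reads the delimited files written by [write_cohort()], checks each table
#' for its required columns and basic row-level validity, and reports all
#' violations together. Lipid/glucose columns carrying a `_mmol` suffix are
#' converted to mg/dL and the conversion logged.
#'
#' @param dir Directory containing `subjects.csv` etc.
#' @param sep Field separator.
#' @return A `metsev_cohort` (without a spec unless `spec.yaml` is present).
#' @export
load_cohort <- function(dir, sep = ",") {
  schema <- cohort_schema()
  errors <- character(0)
  tabs <- list()
  for (name in names(schema)) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (name == "ffq") next  # optional layer
      errors <- c(errors, paste0("missing file: ", name, ".csv"))
      next
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (name == "subjects") {
      for (mm in grep("_mmol$", names(df), value = TRUE)) {
        base <- sub("_mmol$", "", mm)
        analyte <- if (base == "tag") "triglycerides" else
          if (base == "glucose") "glucose" else "cholesterol"
        df[[base]] <- to_mgdl(df[[mm]], analyte, "mmol/l")
        df[[mm]] <- NULL
      }
    }
    missing_cols <- setdiff(schema[[name]], names(df))
    if (length(missing_cols) > 0) {
      errors <- c(errors, paste0(name, ": missing column(s) ",
                                 paste(missing_cols, collapse = ", ")))
    }
    tabs[[name]] <- df
  }
  if (length(errors) > 0) {
    stop("cohort schema violations:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  subj <- tabs$subjects
  bad_rows <- which(subj$bmi <= 0 | subj$age <= 0 |
                      (!is.na(subj$hdl) & subj$hdl <= 0))
  if (length(bad_rows) > 0) {
    stop("invalid subject rows (non-positive age/BMI/HDL): ",
         paste(utils::head(bad_rows, 10), collapse = ", "), call. = FALSE)
  }
  if ("latent_tertile" %in% names(subj)) {
    subj$latent_tertile <- factor(subj$latent_tertile,
                                  levels = c("T1", "T2", "T3"))
  }
  spec <- NULL
  spec_path <- file.path(dir, "spec.yaml")
  if (file.exists(spec_path)) spec <- yaml::read_yaml(spec_path)
  structure(list(subjects = subj, activity = tabs$activity,
                 sedentary = tabs$sedentary, bdi = tabs$bdi,
                 ffq = tabs$ffq, spec = spec),
            class = "metsev_cohort")
}

#' Write analysis outputs (tables, flow, scores)
#'
#' @param tables Named list of table data frames (from [build_tables()]).
#' @param flow Exclusion-flow data frame.
#' @param scores Scored/analysed subject table (or `NULL`).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(tables, flow, scores = NULL, dir = "results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(flow, file.path(dir, "exclusion_flow.csv"),
                   row.names = FALSE)
  if (!is.null(scores)) {
    utils::write.csv(scores, file.path(dir, "scored_subjects.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
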
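# Survey cohort ingestion, derived variables, complete-case filtering
# and risk scoring.

COHORT_COLUMNS <- c("id", "age", "sex", "smoker", "sbp1", "sbp2", "dbp1",
                    "dbp2", "height_cm", "weight_kg", "bmi", "glucose",
                    "residence", "prior_cvd")

HEIGHT_GUARD <- c(100, 250)
WEIGHT_GUARD <- c(10, 500)  # implied by the BMI and height guards
GLUCOSE_GUARD <- c(0.5, 100)

#' Read a survey cohort from CSV
#'
#' Expects the cohort CSV dialect: header
#' `id,age,sex,smoker,sbp1,sbp2,dbp1,dbp2,height_cm,weight_kg,bmi,glucose,residence,prior_cvd`,
#' empty fields meaning missing, `sex` in `male`/`female`, booleans as 0/1,
#' `residence` in `urban`/`rural`.  Ids must be unique; provided numeric
#' values must fall within plausibility guards.
#'
#' @param path Path to the cohort CSV.
#' @return Data frame of class `survey_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) cr_abort(paste("cohort file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss)) {
    cr_abort(sprintf("cohort file %s missing column(s): %s",
                     path, paste(miss, collapse = ", ")))
  }
  df <- df[COHORT_COLUMNS]
  df$id <- as.character(df$id)
  for (col in c("sbp1", "sbp2", "dbp1", "dbp2", "height_cm", "weight_kg",
                "bmi", "glucose")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$age <- as.integer(df$age)
  df$smoker <- as_boolean(df$smoker, "smoker")
  df$prior_cvd <- as_boolean(df$prior_cvd, "prior_cvd")
  validate_cohort(df)
}

as_boolean <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- rep(NA, length(x))
  v[x %in% c(1, "1", "TRUE", "true")] <- TRUE
  v[x %in% c(0, "0", "FALSE", "false")] <- FALSE
  bad <- !is.na(x) & is.na(v)
  if (any(bad)) {
    cr_abort(sprintf("column %s has non-boolean value(s), e.g. %s",
                     what, paste(utils::head(unique(x[bad]), 3), collapse = ", ")))
  }
  v
}

guard_check <- function(df, col, guard, errs) {
  x <- df[[col]]
  bad <- which(!is.na(x) & (x < guard[1] | x > guard[2]))
  if (length(bad)) {
    c(errs, sprintf("%s outside [%g, %g] for id(s) %s", col, guard[1], guard[2],
                    paste(utils::head(df$id[bad], 5), collapse = ", ")))
  } else errs
}

#' Validate a survey cohort
#'
#' Checks id uniqueness, category labels and plausibility guards on every
#' provided numeric value (missing values are allowed everywhere except
#' `id`).
#'
#' @param df Cohort data frame with the columns of [read_cohort()].
#' @return The validated data frame, classed `survey_cohort`.
#' @export
validate_cohort <- function(df) {
  errs <- character()
  if (anyNA(df$id)) errs <- c(errs, "missing id(s)")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    errs <- c(errs, sprintf("duplicated id(s): %s",
                            paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad_sex <- which(!is.na(df$sex) & !(df$sex %in% c("male", "female")))
  if (length(bad_sex)) {
    errs <- c(errs, sprintf("invalid sex for id(s) %s",
                            paste(utils::head(df$id[bad_sex], 5), collapse = ", ")))
  }
  bad_res <- which(!is.na(df$residence) &
                     !(df$residence %in% c("urban", "rural")))
  if (length(bad_res)) {
    errs <- c(errs, sprintf("invalid residence for id(s) %s",
                            paste(utils::head(df$id[bad_res], 5), collapse = ", ")))
  }
  bad_age <- which(!is.na(df$age) & (df$age < AGE_MIN | df$age > 120))
  if (length(bad_age)) {
    errs <- c(errs, sprintf("age outside [%d, 120] for id(s) %s", AGE_MIN,
                            paste(utils::head(df$id[bad_age], 5), collapse = ", ")))
  }
  for (col in c("sbp1", "sbp2")) errs <- guard_check(df, col, SBP_GUARD, errs)
  for (col in c("dbp1", "dbp2")) errs <- guard_check(df, col, DBP_GUARD, errs)
  errs <- guard_check(df, "height_cm", HEIGHT_GUARD, errs)
  errs <- guard_check(df, "weight_kg", WEIGHT_GUARD, errs)
  errs <- guard_check(df, "bmi", BMI_GUARD, errs)
  errs <- guard_check(df, "glucose", GLUCOSE_GUARD, errs)
  if (length(errs)) cr_abort(paste(errs, collapse = "; "))
  class(df) <- c("survey_cohort", "data.frame")
  df
}

#' Write a cohort in the cohort CSV dialect
#'
#' Booleans are written as 0/1 and missing values as empty fields, so the
#' file round-trips through [read_cohort()].
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[COHORT_COLUMNS]
  out$smoker <- as.integer(out$smoker)
  out$prior_cvd <- as.integer(out$prior_cvd)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Final blood pressure as the mean of two readings
#'
#' Survey protocol takes two seated readings and uses their mean as the
#' final value.  When only one reading is available it is used as-is and
#' flagged; when both are missing the result is missing (not an error).
#'
#' @param reading1,reading2 Numeric vectors, mm Hg.
#' @return Numeric vector of final values with attribute
#'   `"single_reading"`, a logical vector marking one-reading fallbacks.
#' @examples
#' mean_bp(120, 130)        # 125
#' mean_bp(120, NA)         # 120, flagged
#' @export
mean_bp <- function(reading1, reading2) {
  out <- rowMeans(cbind(reading1, reading2), na.rm = TRUE)
  out[is.na(reading1) & is.na(reading2)] <- NA_real_
  attr(out, "single_reading") <- xor(is.na(reading1), is.na(reading2))
  out
}

#' Body-mass index from height and weight
#'
#' @param height_cm Height in centimetres, > 0.
#' @param weight_kg Weight in kilograms, > 0.
#' @return BMI in kg/m2 (`NA` where either input is missing).
#' @examples
#' compute_bmi(170, 70)
#' @export
compute_bmi <- function(height_cm, weight_kg) {
  bad <- which((!is.na(height_cm) & height_cm <= 0) |
                 (!is.na(weight_kg) & weight_kg <= 0))
  if (length(bad)) {
    cr_abort(sprintf("nonpositive height or weight at position(s) %s",
                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  weight_kg / (height_cm / 100)^2
}

# Derive the analysis variables: final BP, final BMI (direct bmi field
# takes precedence over height/weight) and the age band.
prepare_cohort <- function(cohort, age_policy = "exclude") {
  df <- as.data.frame(cohort)
  sbp <- mean_bp(df$sbp1, df$sbp2)
  dbp <- mean_bp(df$dbp1, df$dbp2)
  df$sbp_mean <- as.numeric(sbp)
  df$dbp_mean <- as.numeric(dbp)
  df$sbp_single_reading <- attr(sbp, "single_reading")
  df$dbp_single_reading <- attr(dbp, "single_reading")
  bmi_hw <- compute_bmi(df$height_cm, df$weight_kg)
  df$bmi_final <- ifelse(!is.na(df$bmi), df$bmi, bmi_hw)
  ab <- bin_age(df$age, policy = age_policy)
  df$age_band <- as.character(ab)
  df$age_clamped <- attr(ab, "clamped")
  df
}

#' Complete-case filter with an exclusion report
#'
#' Drops records that cannot be scored on the chart: optionally those with
#' prior CVD (the charts apply to people without established disease),
#' those unscorable by age under the chosen policy, and those missing any
#' of smoking status, final SBP, final DBP or final BMI.  Each dropped
#' record is counted under exactly one reason, the first that applies in
#' the order `prior_cvd`, `age_policy`, `smoking`, `sbp`, `dbp`, `bmi`.
#'
#' @param cohort A cohort data frame (raw or from [prepare_cohort]).
#' @param age_policy Passed to [bin_age()].
#' @param drop_prior_cvd Drop records with `prior_cvd == TRUE` (default
#'   `TRUE`); records with missing `prior_cvd` are kept.
#' @return List with `retained` (the filtered, prepared data frame) and
#'   `report` (named integer vector of exclusion counts plus `n_input` and
#'   `n_retained`).
#' @export
complete_case_filter <- function(cohort, age_policy = c("exclude", "clamp"),
                                 drop_prior_cvd = TRUE) {
  age_policy <- match.arg(age_policy)
  df <- if ("sbp_mean" %in% names(cohort)) as.data.frame(cohort)
        else prepare_cohort(cohort, age_policy)
  reason <- rep(NA_character_, nrow(df))
  mark <- function(cond, label) {
    hit <- is.na(reason) & !is.na(cond) & cond
    reason[hit] <<- label
  }
  if (drop_prior_cvd) mark(!is.na(df$prior_cvd) & df$prior_cvd, "prior_cvd")
  mark(is.na(df$age_band), "age_policy")
  mark(is.na(df$smoker), "smoking")
  mark(is.na(df$sbp_mean), "sbp")
  mark(is.na(df$dbp_mean), "dbp")
  mark(is.na(df$bmi_final), "bmi")

  labels <- c("prior_cvd", "age_policy", "smoking", "sbp", "dbp", "bmi")
  report <- vapply(labels, function(l) sum(reason == l, na.rm = TRUE), 0L)
  report <- c(report, n_input = nrow(df), n_retained = sum(is.na(reason)))
  list(retained = df[is.na(reason), , drop = FALSE], report = report)
}

#' Clinical threshold flags
#'
#' Hypertension is final BP >= 140/90 (SBP >= 140 or DBP >= 90, both
#' inclusive); severe hypertension is >= 160/100 with the same OR
#' semantics; hyperglycaemia is random blood glucose >= 11.1 mmol/L;
#' overweight/obesity is BMI >= `overweight_threshold`.  A flag whose
#' inputs are missing is missing, never silently `FALSE` (an OR is still
#' `TRUE` when one present input already crosses its threshold).
#'
#' @param df Data frame with `sbp_mean`, `dbp_mean`, `bmi_final`,
#'   `glucose` (any may be absent or `NA`).
#' @param overweight_threshold BMI cut-off, kg/m2; default 25.
#' @return Data frame with logical columns `htn`, `severe_htn`,
#'   `hyperglycaemia`, `overweight_obesity`.
#' @examples
#' derive_flags(data.frame(sbp_mean = 138, dbp_mean = 92,
#'                         bmi_final = 24, glucose = 12))
#' @export
derive_flags <- function(df, overweight_threshold = 25) {
  get <- function(col) if (col %in% names(df)) df[[col]] else NA_real_
  sbp <- get("sbp_mean"); dbp <- get("dbp_mean")
  data.frame(
    htn = (sbp >= 140) | (dbp >= 90),
    severe_htn = (sbp >= 160) | (dbp >= 100),
    hyperglycaemia = get("glucose") >= 11.1,
    overweight_obesity = get("bmi_final") >= overweight_threshold
  )
}

#' Score a cohort on a risk chart
#'
#' Runs the full per-record pipeline: derive final BP and BMI, apply the
#' complete-case filter, look up 10-year risk on the chart, categorise it
#' and derive the clinical flags.  Retained records keep their input
#' order.
#'
#' @param cohort A cohort data frame ([read_cohort()] dialect).
#' @param chart A validated `risk_chart`.
#' @param age_policy,drop_prior_cvd Passed to [complete_case_filter()].
#' @param overweight_threshold Passed to [derive_flags()].
#' @return Data frame of class `scored_cohort`: the retained records plus
#'   `sbp_mean`, `dbp_mean`, `bmi_final`, `risk_percent`, `risk_category`,
#'   the four flags and `scorable`.  The exclusion report is attached as
#'   attribute `"exclusions"`.
#' @export
score_cohort <- function(cohort, chart, age_policy = c("exclude", "clamp"),
                         drop_prior_cvd = TRUE, overweight_threshold = 25) {
  age_policy <- match.arg(age_policy)
  df <- prepare_cohort(cohort, age_policy)
  fl <- complete_case_filter(df, age_policy, drop_prior_cvd)
  kept <- fl$retained
  if (nrow(kept)) {
    profiles <- data.frame(age = kept$age, sex = kept$sex,
                           smoker = kept$smoker, sbp = kept$sbp_mean,
                           bmi = kept$bmi_final)
    risk <- tryCatch(lookup_risk(profiles, chart, age_policy),
                     chartrisk_error = function(e) {
                       cr_abort(paste("while scoring cohort:",
                                      conditionMessage(e)))
                     })
    kept$risk_percent <- as.numeric(risk)
    kept$risk_category <- categorize_risk(kept$risk_percent)
  } else {
    kept$risk_percent <- numeric(0)
    kept$risk_category <- categorize_risk(numeric(0))
  }
  kept <- cbind(kept, derive_flags(kept, overweight_threshold))
  kept$scorable <- !is.na(kept$risk_percent)
  rownames(kept) <- NULL
  attr(kept, "exclusions") <- fl$report
  class(kept) <- c("scored_cohort", "data.frame")
  kept
}

#' Exclusion report of a scored cohort
#'
#' @param scored A `scored_cohort` from [score_cohort()].
#' @return Named integer vector of exclusion counts.
#' @export
exclusion_report <- function(scored) attr(scored, "exclusions")
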
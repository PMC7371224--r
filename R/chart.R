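# Risk chart container: a validated 700-cell lookup table
# (sex x smoker x 7 age bands x 5 SBP bands x 5 BMI bands).

chart_key <- function(sex, smoker, age_band, sbp_band, bmi_band) {
  paste(sex, as.integer(smoker), age_band, sbp_band, bmi_band, sep = "|")
}

all_chart_cells <- function() {
  g <- expand.grid(sex = c("male", "female"), smoker = c(0L, 1L),
                   age_band = AGE_BAND_LABELS, sbp_band = SBP_BAND_LABELS,
                   bmi_band = BMI_BAND_LABELS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(g$sex, g$smoker, match(g$age_band, AGE_BAND_LABELS),
          match(g$sbp_band, SBP_BAND_LABELS),
          match(g$bmi_band, BMI_BAND_LABELS)), , drop = FALSE]
}

#' Construct and validate a risk chart
#'
#' A risk chart maps every combination of sex, smoking status, age band,
#' SBP band and BMI band to a 10-year CVD risk percentage.  Validation
#' requires exactly the full 2 x 2 x 7 x 5 x 5 = 700 cells, no duplicates,
#' and every risk in \[0, 100\].
#'
#' @param cells Data frame with columns `sex` (`male`/`female`), `smoker`
#'   (0/1), `age_band`, `sbp_band`, `bmi_band` (labels as in
#'   [age_bands()], [sbp_bands()], [bmi_bands()]) and `risk_percent`.
#' @return An object of class `risk_chart` (a data frame of the 700 cells
#'   in canonical order, with a lookup key attribute).
#' @seealso [load_chart()], [lookup_risk()], [generate_chart_fixture()]
#' @export
as_risk_chart <- function(cells) {
  need <- c("sex", "smoker", "age_band", "sbp_band", "bmi_band", "risk_percent")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    cr_abort(paste("chart is missing column(s):", paste(miss, collapse = ", ")))
  }
  cells$sex <- as.character(cells$sex)
  cells$smoker <- as.integer(cells$smoker)
  cells$risk_percent <- as.numeric(cells$risk_percent)

  bad_lab <- !(cells$sex %in% c("male", "female")) |
    !(cells$smoker %in% c(0L, 1L)) |
    !(cells$age_band %in% AGE_BAND_LABELS) |
    !(cells$sbp_band %in% SBP_BAND_LABELS) |
    !(cells$bmi_band %in% BMI_BAND_LABELS)
  if (any(bad_lab)) {
    cr_abort(sprintf("chart row(s) with unrecognised coordinates: %s",
                     paste(utils::head(which(bad_lab), 5), collapse = ", ")))
  }
  if (any(is.na(cells$risk_percent) | cells$risk_percent < 0 |
          cells$risk_percent > 100)) {
    cr_abort("chart risk_percent values must all lie in [0, 100]")
  }

  key <- chart_key(cells$sex, cells$smoker, cells$age_band,
                   cells$sbp_band, cells$bmi_band)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    cr_abort(sprintf("duplicated chart cell(s): %s",
                     paste(utils::head(dup, 5), collapse = "; ")))
  }
  full <- all_chart_cells()
  full_key <- chart_key(full$sex, full$smoker, full$age_band,
                        full$sbp_band, full$bmi_band)
  absent <- setdiff(full_key, key)
  if (length(absent)) {
    cr_abort(sprintf("chart is missing %d cell(s), e.g.: %s",
                     length(absent), paste(utils::head(absent, 5), collapse = "; ")))
  }

  out <- cells[match(full_key, key), need, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "key") <- full_key
  class(out) <- c("risk_chart", "data.frame")
  out
}

#' Read a risk chart from CSV
#'
#' Expects the chart CSV dialect: header
#' `sex,smoker,age_band,sbp_band,bmi_band,risk_percent`, sex in
#' `male`/`female`, smoker in 0/1, band labels as printed by
#' [write_chart()], UTF-8 with `.` as decimal separator.
#'
#' @param path Path to the chart CSV file.
#' @return A validated [as_risk_chart()] object.
#' @export
load_chart <- function(path) {
  if (!file.exists(path)) cr_abort(paste("chart file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_risk_chart(df)
}

#' Write a risk chart to CSV
#'
#' @param chart A `risk_chart`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "risk_chart"))
  utils::write.csv(as.data.frame(chart), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.risk_chart <- function(x, ...) {
  cat("Non-laboratory 10-year CVD risk chart: 700 cells\n")
  cat(sprintf("  risk range: %.1f%% to %.1f%%\n",
              min(x$risk_percent), max(x$risk_percent)))
  invisible(x)
}

#' Look up 10-year risk for chartable profiles
#'
#' Bins each profile's age, SBP and BMI onto the chart axes and reads the
#' unique matching cell.  A profile is unscorable (risk `NA`) only when its
#' age falls off the chart under `age_policy = "exclude"`.
#'
#' @param profiles Data frame with columns `age` (years), `sex`
#'   (`male`/`female`), `smoker` (logical or 0/1), `sbp` (mm Hg) and `bmi`
#'   (kg/m2).  All values must be non-missing and within plausibility
#'   guards.
#' @param chart A validated `risk_chart`.
#' @param age_policy Passed to [bin_age()].
#' @return Numeric vector of risk percentages, `NA` for unscorable ages,
#'   with attribute `"clamped"` marking profiles scored via age clamping.
#' @examples
#' chart <- generate_chart_fixture()
#' lookup_risk(data.frame(age = 62, sex = "male", smoker = TRUE,
#'                        sbp = 165, bmi = 27), chart)
#' @export
lookup_risk <- function(profiles, chart, age_policy = c("exclude", "clamp")) {
  age_policy <- match.arg(age_policy)
  stopifnot(inherits(chart, "risk_chart"))
  need <- c("age", "sex", "smoker", "sbp", "bmi")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    cr_abort(paste("profiles missing column(s):", paste(miss, collapse = ", ")))
  }
  if (!all(profiles$sex %in% c("male", "female"))) {
    cr_abort("profiles$sex must be 'male' or 'female'")
  }
  if (anyNA(profiles[need])) {
    cr_abort("lookup_risk requires complete profiles; filter missing values first")
  }
  ab <- bin_age(profiles$age, policy = age_policy)
  sb <- bin_sbp(profiles$sbp)
  bb <- bin_bmi(profiles$bmi)
  key <- chart_key(profiles$sex, as.integer(as.logical(profiles$smoker)),
                   ab, sb, bb)
  idx <- match(key, attr(chart, "key"))
  out <- chart$risk_percent[idx]
  out[is.na(ab)] <- NA_real_
  attr(out, "clamped") <- attr(ab, "clamped")
  out
}
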
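# Axis definitions for the non-laboratory risk chart.
#
# All printed chart bands are half-open [lower, upper): "120-139" means
# [120, 140), "20-24" means [20, 25).  The overlap in the printed BMI axis
# ("30-35 and >=35") is resolved as [30, 35) and [35, Inf), mirroring the
# SBP axis ("160 to <180 and >=180").

AGE_BAND_LABELS <- c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74")
SBP_BAND_LABELS <- c("lt120", "120-139", "140-159", "160-179", "ge180")
BMI_BAND_LABELS <- c("lt20", "20-24", "25-29", "30-34", "ge35")
RISK_CATEGORY_LEVELS <- c("very_low", "low", "moderate", "high", "very_high")

AGE_BREAKS <- seq(40, 75, by = 5)      # [40,45) ... [70,75)
SBP_BREAKS <- c(0, 120, 140, 160, 180) # upper band open-ended
BMI_BREAKS <- c(0, 20, 25, 30, 35)
RISK_BREAKS <- c(0, 5, 10, 20, 30)     # very_low [0,5) ... very_high [30,Inf)

# plausibility guards; violations are errors, not missingness
SBP_GUARD <- c(50, 300)
DBP_GUARD <- c(30, 200)
BMI_GUARD <- c(10, 80)
AGE_MIN <- 40

#' Chart axis band tables
#'
#' The three binning axes of the non-laboratory 10-year CVD risk chart:
#' seven 5-year age bands covering \[40, 75), five systolic blood pressure
#' bands covering \[0, Inf) and five body-mass-index bands covering
#' \[0, Inf).  Bands are half-open `[lower, upper)`.
#'
#' @return A data frame with columns `label`, `lower` (inclusive) and
#'   `upper` (exclusive; `Inf` for the top SBP/BMI band).
#' @examples
#' age_bands()
#' sbp_bands()
#' @export
age_bands <- function() {
  data.frame(label = AGE_BAND_LABELS,
             lower = AGE_BREAKS[-8], upper = AGE_BREAKS[-1])
}

#' @rdname age_bands
#' @export
sbp_bands <- function() {
  data.frame(label = SBP_BAND_LABELS,
             lower = SBP_BREAKS, upper = c(SBP_BREAKS[-1], Inf))
}

#' @rdname age_bands
#' @export
bmi_bands <- function() {
  data.frame(label = BMI_BAND_LABELS,
             lower = BMI_BREAKS, upper = c(BMI_BREAKS[-1], Inf))
}

cr_abort <- function(msg, class = "chartrisk_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Bin age into 5-year chart bands
#'
#' The chart covers ages 40 to 74 in seven 5-year bands.  Ages of 75 and
#' over fall off the chart: under `policy = "exclude"` (the default) they
#' are returned as `NA` (unscorable); under `policy = "clamp"` they are
#' assigned to the top 70-74 band and flagged via the `"clamped"`
#' attribute.  Ages below 40 are outside the chart's domain and raise an
#' error.
#'
#' @param age_years Integer vector of ages in years.
#' @param policy `"exclude"` or `"clamp"`, the handling of ages >= 75.
#' @return Character vector of band labels (`NA` where unscorable), with
#'   attributes `"policy"` and `"clamped"` (logical vector) recording the
#'   choice applied.
#' @examples
#' bin_age(c(40, 74))
#' bin_age(80, policy = "clamp")
#' @export
bin_age <- function(age_years, policy = c("exclude", "clamp")) {
  policy <- match.arg(policy)
  bad <- which(!is.na(age_years) & age_years < AGE_MIN)
  if (length(bad)) {
    cr_abort(sprintf("age below %d (chart domain starts at %d) at position(s) %s: %s",
                     AGE_MIN, AGE_MIN,
                     paste(utils::head(bad, 5), collapse = ", "),
                     paste(utils::head(age_years[bad], 5), collapse = ", ")))
  }
  idx <- findInterval(age_years, AGE_BREAKS)  # 8 => age >= 75
  clamped <- !is.na(idx) & idx == 8L & policy == "clamp"
  idx[clamped] <- 7L
  idx[!is.na(idx) & idx == 8L] <- NA_integer_
  out <- AGE_BAND_LABELS[idx]
  attr(out, "policy") <- policy
  attr(out, "clamped") <- clamped
  out
}

bin_on_breaks <- function(x, breaks, labels, guard, what) {
  bad <- which(!is.na(x) & (x < guard[1] | x > guard[2]))
  if (length(bad)) {
    cr_abort(sprintf("%s outside plausibility guard [%g, %g] at position(s) %s: %s",
                     what, guard[1], guard[2],
                     paste(utils::head(bad, 5), collapse = ", "),
                     paste(utils::head(x[bad], 5), collapse = ", ")))
  }
  labels[findInterval(x, breaks)]
}

#' Bin systolic blood pressure into chart bands
#'
#' Bands are `<120`, `120-139`, `140-159`, `160-179` and `>=180` mm Hg,
#' half-open at the upper edge, so 140 falls in `140-159` and 180 in
#' `>=180`.
#'
#' @param sbp_mmHg Numeric vector, mm Hg; must lie within the plausibility
#'   guard \[50, 300\].
#' @return Character vector of band labels.
#' @examples
#' bin_sbp(c(119.9, 140, 180))
#' @export
bin_sbp <- function(sbp_mmHg) {
  bin_on_breaks(sbp_mmHg, SBP_BREAKS, SBP_BAND_LABELS, SBP_GUARD,
                "systolic blood pressure")
}

#' Bin body-mass index into chart bands
#'
#' Bands are `<20`, `20-24`, `25-29`, `30-34` and `>=35` kg/m2, half-open,
#' so 25 falls in `25-29` and 35 in `>=35`.
#'
#' @param bmi_kg_m2 Numeric vector, kg/m2; must lie within the plausibility
#'   guard \[10, 80\].
#' @return Character vector of band labels.
#' @examples
#' bin_bmi(c(19.99, 24.6, 35))
#' @export
bin_bmi <- function(bmi_kg_m2) {
  bin_on_breaks(bmi_kg_m2, BMI_BREAKS, BMI_BAND_LABELS, BMI_GUARD,
                "body-mass index")
}

#' Categorise a 10-year risk percentage
#'
#' Five categories partition the risk scale: very low \[0, 5), low
#' \[5, 10), moderate \[10, 20), high \[20, 30) and very high \[30, Inf).
#' Boundary values fall upward (5 is low, 20 is high, 30 is very high).
#'
#' @param risk_percent Numeric vector of 10-year risk in percent, >= 0.
#' @return Factor with levels `very_low`, `low`, `moderate`, `high`,
#'   `very_high` (`NA` propagated).
#' @examples
#' categorize_risk(c(4.9, 5, 20, 30))
#' @export
categorize_risk <- function(risk_percent) {
  bad <- which(!is.na(risk_percent) & risk_percent < 0)
  if (length(bad)) {
    cr_abort(sprintf("negative risk percent at position(s) %s",
                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  factor(RISK_CATEGORY_LEVELS[findInterval(risk_percent, RISK_BREAKS)],
         levels = RISK_CATEGORY_LEVELS)
}
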
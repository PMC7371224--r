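# Synthetic survey cohorts and monotone chart fixtures, with analytic
# expectations for parameter-recovery testing.
#
# Defaults emulate the marginal structure of a national Bangladeshi
# survey of adults aged >= 40 (n = 6189): age 52.9 (SD 9.9), SBP 119.7
# (15.2), DBP 80.3 (9.5), per-sex BMI 21.4 (3.7) men / 22.3 (4.4) women,
# current smoking 50.7% men / 1.8% women, glucose mean 6.9 SD 3.0,
# urban share 30.2%, per-variable missingness 0.3-0.5% (glucose 1.4%).
# The joint SBP-DBP structure, reading-level measurement noise, heights
# and the prior-CVD rate are synthetic inventions: the emulated survey
# reports marginals only.

#' Configuration of the synthetic cohort generator
#'
#' All parameters have survey-calibrated defaults; see the package
#' vignette for their provenance and which aspects are invented.
#' Truncated-normal ages are floored to integer years, which leaves the
#' probability of each 5-year chart band identical to the continuous
#' distribution's.  Each person receives two SBP and two DBP readings
#' drawn around a person-level true value with independent measurement
#' noise (`reading_sd`); the pipeline's mean-of-two rule recovers the
#' true value up to noise of `reading_sd/sqrt(2)`.
#'
#' @param n Cohort size.
#' @param seed Integer seed giving byte-identical cohorts.
#' @param prop_female Proportion of women.
#' @param age_mean,age_sd,age_min,age_max Target mean and SD of the
#'   observed integer ages (years); the underlying normal is calibrated
#'   so that, after truncation to `[age_min, age_max)` and flooring to
#'   whole years, the generated ages hit these moments.
#' @param sbp_mean,sbp_sd True systolic BP (mm Hg), truncated to the
#'   plausibility guard.
#' @param dbp_mean,dbp_sd,bp_cor True diastolic BP and its correlation
#'   with systolic BP.
#' @param reading_sd Per-reading measurement noise SD (mm Hg).
#' @param bmi_mean_m,bmi_sd_m,bmi_mean_f,bmi_sd_f Per-sex truncated-normal
#'   BMI (kg/m2).
#' @param height_mean_m,height_sd_m,height_mean_f,height_sd_f Per-sex
#'   heights (cm) used to derive weight from BMI.
#' @param smoking_m,smoking_f Per-sex current-smoking prevalence.
#' @param glucose_mean,glucose_sd Random blood glucose (mmol/L), lognormal
#'   matched to this mean and SD.
#' @param urban_prop Proportion urban.
#' @param prior_cvd_rate Proportion with self-reported prior CVD.
#' @param missing_smoker,missing_sbp,missing_dbp,missing_bmi,missing_glucose
#'   Independent per-variable missingness rates (MCAR); BP missingness
#'   removes both readings, BMI missingness removes height and weight.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n = 6189, seed = 1,
                             prop_female = 3365 / 6189,
                             age_mean = 52.9, age_sd = 9.9,
                             age_min = 40, age_max = 120,
                             sbp_mean = 119.7, sbp_sd = 15.2,
                             dbp_mean = 80.3, dbp_sd = 9.5, bp_cor = 0.6,
                             reading_sd = 2,
                             bmi_mean_m = 21.4, bmi_sd_m = 3.7,
                             bmi_mean_f = 22.3, bmi_sd_f = 4.4,
                             height_mean_m = 162, height_sd_m = 6.1,
                             height_mean_f = 151, height_sd_f = 5.6,
                             smoking_m = 0.507, smoking_f = 0.018,
                             glucose_mean = 6.9, glucose_sd = 3.0,
                             urban_prop = 0.302,
                             prior_cvd_rate = 0.03,
                             missing_smoker = 0.003, missing_sbp = 0.004,
                             missing_dbp = 0.004, missing_bmi = 0.005,
                             missing_glucose = 0.014) {
  cfg <- as.list(environment())
  props <- c(cfg$prop_female, cfg$smoking_m, cfg$smoking_f, cfg$urban_prop,
             cfg$prior_cvd_rate, cfg$missing_smoker, cfg$missing_sbp,
             cfg$missing_dbp, cfg$missing_bmi, cfg$missing_glucose)
  if (any(props < 0 | props > 1)) cr_abort("proportions must lie in [0, 1]")
  sds <- c(cfg$age_sd, cfg$sbp_sd, cfg$dbp_sd, cfg$reading_sd, cfg$bmi_sd_m,
           cfg$bmi_sd_f, cfg$height_sd_m, cfg$height_sd_f, cfg$glucose_sd)
  if (any(sds <= 0)) cr_abort("standard deviations must be positive")
  if (cfg$n < 1) cr_abort("n must be >= 1")
  if (cfg$age_min >= cfg$age_max) cr_abort("impossible age truncation bounds")
  if (abs(cfg$bp_cor) >= 1) cr_abort("bp_cor must lie in (-1, 1)")
  # age_mean/age_sd are the target moments of the observed integer ages:
  # calibrate the underlying normal for the >= age_min truncation and the
  # flooring to whole years (floor subtracts ~1/2 from the mean and adds
  # ~1/12 to the variance).  SBP/BMI guards sit 4+ SDs out, so their
  # truncation correction is negligible and they are used directly.
  cal <- tnorm_calibrate(cfg$age_mean + 0.5,
                         sqrt(max(cfg$age_sd^2 - 1 / 12, 0.01)),
                         cfg$age_min, cfg$age_max)
  cfg$age_mu <- unname(cal["mu"])
  cfg$age_sigma <- unname(cal["sigma"])
  class(cfg) <- "generator_config"
  cfg
}

# Moments of a normal truncated to [lower, upper].
tnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying (mu, sigma) such that the truncated distribution has the
# requested moments.  The survey reports moments of the observed
# (truncated) variable, so the generator must invert the truncation.
tnorm_calibrate <- function(target_mean, target_sd, lower, upper) {
  obj <- function(par) {
    m <- tnorm_moments(par[1], exp(par[2]), lower, upper)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-6) {
    cr_abort(sprintf(
      "cannot calibrate a truncated normal on [%g, %g] to mean %g, sd %g",
      lower, upper, target_mean, target_sd))
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Exact truncated-normal sampling by inverse CDF.
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) cr_abort("impossible truncation bounds")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic survey cohort
#'
#' Deterministic given the config's seed; marginals converge to the
#' configured parameters; missingness is applied independently per
#' variable (missing completely at random).
#'
#' @param config A [generator_config()].
#' @return Data frame of class `survey_cohort` in the cohort CSV dialect.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 100, seed = 7))
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n
    female <- stats::runif(n) < cfg$prop_female
    sex <- ifelse(female, "female", "male")

    age <- as.integer(floor(rtnorm(n, cfg$age_mu, cfg$age_sigma,
                                   cfg$age_min, cfg$age_max)))

    sbp_true <- rtnorm(n, cfg$sbp_mean, cfg$sbp_sd, SBP_GUARD[1], SBP_GUARD[2])
    cond_sd <- cfg$dbp_sd * sqrt(1 - cfg$bp_cor^2)
    dbp_true <- cfg$dbp_mean +
      cfg$bp_cor * cfg$dbp_sd / cfg$sbp_sd * (sbp_true - cfg$sbp_mean) +
      stats::rnorm(n, 0, cond_sd)
    dbp_true <- pmin(pmax(dbp_true, DBP_GUARD[1]), DBP_GUARD[2])
    reading <- function(true) {
      pmin(pmax(true + stats::rnorm(n, 0, cfg$reading_sd), SBP_GUARD[1]),
           SBP_GUARD[2])
    }
    dreading <- function(true) {
      pmin(pmax(true + stats::rnorm(n, 0, cfg$reading_sd), DBP_GUARD[1]),
           DBP_GUARD[2])
    }
    sbp1 <- reading(sbp_true); sbp2 <- reading(sbp_true)
    dbp1 <- dreading(dbp_true); dbp2 <- dreading(dbp_true)

    bmi <- ifelse(female,
                  rtnorm(n, cfg$bmi_mean_f, cfg$bmi_sd_f, BMI_GUARD[1], BMI_GUARD[2]),
                  rtnorm(n, cfg$bmi_mean_m, cfg$bmi_sd_m, BMI_GUARD[1], BMI_GUARD[2]))
    height <- ifelse(female,
                     rtnorm(n, cfg$height_mean_f, cfg$height_sd_f, 100, 250),
                     rtnorm(n, cfg$height_mean_m, cfg$height_sd_m, 100, 250))
    height <- round(height, 1)
    # full-precision weight from the rounded height, so the pipeline's
    # derived BMI reproduces the drawn BMI exactly (guard-safe)
    weight <- bmi * (height / 100)^2

    smoker <- stats::runif(n) < ifelse(female, cfg$smoking_f, cfg$smoking_m)
    lp <- lnorm_params(cfg$glucose_mean, cfg$glucose_sd)
    glucose <- pmin(stats::rlnorm(n, lp["meanlog"], lp["sdlog"]),
                    GLUCOSE_GUARD[2])
    residence <- ifelse(stats::runif(n) < cfg$urban_prop, "urban", "rural")
    prior_cvd <- stats::runif(n) < cfg$prior_cvd_rate

    drop <- function(rate) stats::runif(n) < rate
    smoker[drop(cfg$missing_smoker)] <- NA
    m_sbp <- drop(cfg$missing_sbp); sbp1[m_sbp] <- NA; sbp2[m_sbp] <- NA
    m_dbp <- drop(cfg$missing_dbp); dbp1[m_dbp] <- NA; dbp2[m_dbp] <- NA
    m_bmi <- drop(cfg$missing_bmi); height[m_bmi] <- NA; weight[m_bmi] <- NA
    glucose[drop(cfg$missing_glucose)] <- NA

    df <- data.frame(
      id = sprintf("P%06d", seq_len(n)), age = age, sex = sex,
      smoker = smoker,
      sbp1 = round(sbp1, 1), sbp2 = round(sbp2, 1),
      dbp1 = round(dbp1, 1), dbp2 = round(dbp2, 1),
      height_cm = height, weight_kg = weight,
      bmi = NA_real_, glucose = round(glucose, 1),
      residence = residence, prior_cvd = prior_cvd
    )
    validate_cohort(df)
  })
}

#' Generate a monotone chart fixture
#'
#' Builds a complete 700-cell risk chart with multiplicative structure:
#' `risk = base_risk x age_mult^(age band - 1) x sbp_mult^(SBP band - 1)
#' x bmi_mult^(BMI band - 1) x smoke_mult^smoker`, capped at `cap`.
#' Multipliers >= 1 make the chart non-decreasing along every axis.  The
#' defaults give a low-risk chart whose top cell (male smoker, 70-74,
#' >=180, >=35) is well above 30% while a typical middle-aged
#' normotensive non-smoker sits near 2%.
#'
#' @param base_risk Risk percent of the reference cell (female
#'   non-smoker, 40-44, <120, <20).
#' @param age_mult,sbp_mult,bmi_mult,smoke_mult Per-step multipliers.
#' @param cap Upper cap in percent.
#' @return A validated `risk_chart`.
#' @examples
#' chart <- generate_chart_fixture()
#' max(chart$risk_percent) > 30
#' @export
generate_chart_fixture <- function(base_risk = 0.8, age_mult = 1.5,
                                   sbp_mult = 1.35, bmi_mult = 1.15,
                                   smoke_mult = 1.6, cap = 100) {
  cells <- all_chart_cells()
  risk <- base_risk *
    age_mult^(match(cells$age_band, AGE_BAND_LABELS) - 1) *
    sbp_mult^(match(cells$sbp_band, SBP_BAND_LABELS) - 1) *
    bmi_mult^(match(cells$bmi_band, BMI_BAND_LABELS) - 1) *
    smoke_mult^cells$smoker
  cells$risk_percent <- pmin(risk, cap)
  as_risk_chart(cells)
}

# Band occupancy probabilities of a truncated normal over half-open
# [lower, upper) bands; truncation renormalises within [tlo, thi].
band_probs <- function(mean, sd, lowers, uppers, tlo, thi) {
  denom <- stats::pnorm(thi, mean, sd) - stats::pnorm(tlo, mean, sd)
  lo <- pmax(lowers, tlo)
  hi <- pmin(uppers, thi)
  p <- (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)) / denom
  p[hi <= lo] <- 0
  p / sum(p)
}

# Measured-BP joint distribution implied by a config: mean-of-two
# readings adds reading_sd^2/2 to each variance; the true-value
# covariance is unchanged.
measured_bp_params <- function(cfg) {
  vs <- cfg$sbp_sd^2 + cfg$reading_sd^2 / 2
  vd <- cfg$dbp_sd^2 + cfg$reading_sd^2 / 2
  list(mu_s = cfg$sbp_mean, mu_d = cfg$dbp_mean,
       sd_s = sqrt(vs), sd_d = sqrt(vd),
       cov = cfg$bp_cor * cfg$sbp_sd * cfg$dbp_sd)
}

# P(measured SBP in [lo, hi) AND condition), where condition is
# "sbp >= s_thr OR dbp >= d_thr" (severe/htn style), by integrating the
# conditional-normal probability of the DBP exceedance over SBP.
p_sbp_band_and_bp_exceed <- function(bp, lo, hi, s_thr, d_thr) {
  sd_cond <- sqrt(bp$sd_d^2 - bp$cov^2 / bp$sd_s^2)
  f <- function(s) {
    mu_c <- bp$mu_d + bp$cov / bp$sd_s^2 * (s - bp$mu_s)
    p_d <- stats::pnorm(d_thr, mu_c, sd_cond, lower.tail = FALSE)
    stats::dnorm(s, bp$mu_s, bp$sd_s) * ifelse(s >= s_thr, 1, p_d)
  }
  lo <- max(lo, bp$mu_s - 12 * bp$sd_s)
  hi <- min(hi, bp$mu_s + 12 * bp$sd_s)
  if (hi <= lo) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}

#' Analytic expectations for a generated-and-scored cohort
#'
#' Computes, by exact band-occupancy products and numerical integration
#' over the config's distributions, the expected risk-category
#' distribution and eligibility/flag prevalences of a cohort generated
#' with `config` and scored on `chart` — conditional on being scorable
#' (age on-chart under the exclude policy; MCAR missingness and prior-CVD
#' exclusion are independent of the risk factors, so they do not shift
#' conditional prevalences).  Used as the oracle in parameter-recovery
#' tests.
#'
#' @param config A [generator_config()].
#' @param chart A validated `risk_chart`.
#' @return List with `category` (data frame: category x expected
#'   proportion for men, women, total) and `rules` (data frame: expected
#'   proportion eligible under rules A, B, C plus `htn` and `severe_htn`,
#'   by the same strata).
#' @export
expected_prevalences <- function(config, chart) {
  stopifnot(inherits(config, "generator_config"),
            inherits(chart, "risk_chart"))
  cfg <- config
  age_hi <- min(cfg$age_max, 75)  # scorable ages only
  p_age <- band_probs(cfg$age_mu, cfg$age_sigma, AGE_BREAKS[-8],
                      AGE_BREAKS[-1], cfg$age_min, age_hi)
  bp <- measured_bp_params(cfg)
  sbp_lo <- c(SBP_GUARD[1], 120, 140, 160, 180)
  sbp_hi <- c(120, 140, 160, 180, SBP_GUARD[2])
  p_sbp <- band_probs(bp$mu_s, bp$sd_s, sbp_lo, sbp_hi,
                      SBP_GUARD[1], SBP_GUARD[2])
  p_bmi_sex <- list(
    male = band_probs(cfg$bmi_mean_m, cfg$bmi_sd_m,
                      c(BMI_GUARD[1], BMI_BREAKS[-1]),
                      c(BMI_BREAKS[-1], BMI_GUARD[2]),
                      BMI_GUARD[1], BMI_GUARD[2]),
    female = band_probs(cfg$bmi_mean_f, cfg$bmi_sd_f,
                        c(BMI_GUARD[1], BMI_BREAKS[-1]),
                        c(BMI_BREAKS[-1], BMI_GUARD[2]),
                        BMI_GUARD[1], BMI_GUARD[2])
  )
  smoke_sex <- c(male = cfg$smoking_m, female = cfg$smoking_f)

  # P(SBP band & severe), P(SBP band & htn): same for both sexes
  denom_s <- stats::pnorm(SBP_GUARD[2], bp$mu_s, bp$sd_s) -
    stats::pnorm(SBP_GUARD[1], bp$mu_s, bp$sd_s)
  p_band_severe <- vapply(seq_along(sbp_lo), function(i) {
    p_sbp_band_and_bp_exceed(bp, sbp_lo[i], sbp_hi[i], 160, 100) / denom_s
  }, 0)
  p_htn <- sum(vapply(seq_along(sbp_lo), function(i) {
    p_sbp_band_and_bp_exceed(bp, sbp_lo[i], sbp_hi[i], 140, 90) / denom_s
  }, 0))
  p_severe <- sum(p_band_severe)

  cells <- as.data.frame(chart)
  ai <- match(cells$age_band, AGE_BAND_LABELS)
  si <- match(cells$sbp_band, SBP_BAND_LABELS)
  bi <- match(cells$bmi_band, BMI_BAND_LABELS)
  cat_of_cell <- categorize_risk(cells$risk_percent)

  per_sex <- function(sex) {
    sel <- cells$sex == sex
    p_smoke <- ifelse(cells$smoker[sel] == 1, smoke_sex[[sex]],
                      1 - smoke_sex[[sex]])
    p_cell <- p_smoke * p_age[ai[sel]] * p_sbp[si[sel]] *
      p_bmi_sex[[sex]][bi[sel]]
    cat_p <- vapply(RISK_CATEGORY_LEVELS, function(cl) {
      sum(p_cell[cat_of_cell[sel] == cl])
    }, 0)
    high <- cells$risk_percent[sel] >= 20
    rule_a <- sum(p_cell[high])
    # P(not-A cell AND severe): replace the cell's SBP-band factor by the
    # joint band-and-severe probability
    p_cell_sev <- p_smoke * p_age[ai[sel]] * p_band_severe[si[sel]] *
      p_bmi_sex[[sex]][bi[sel]]
    rule_b <- rule_a + sum(p_cell_sev[!high])
    list(category = cat_p,
         rules = c(A = rule_a, B = rule_b, C = p_htn,
                   htn = p_htn, severe_htn = p_severe))
  }
  men <- per_sex("male")
  women <- per_sex("female")
  w <- cfg$prop_female
  category <- data.frame(
    category = factor(RISK_CATEGORY_LEVELS, levels = RISK_CATEGORY_LEVELS),
    men = unname(men$category), women = unname(women$category),
    total = unname((1 - w) * men$category + w * women$category)
  )
  rules <- data.frame(
    rule = names(men$rules),
    men = unname(men$rules), women = unname(women$rules),
    total = unname((1 - w) * men$rules + w * women$rules)
  )
  list(category = category, rules = rules)
}
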
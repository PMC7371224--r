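# Independent brute-force oracles and in-code fixtures.

# Interval-membership binning oracle: linear scan over half-open bands.
oracle_bin <- function(x, bands) {
  vapply(x, function(v) {
    hit <- which(v >= bands$lower & v < bands$upper)
    if (length(hit) != 1) NA_character_ else bands$label[hit]
  }, character(1))
}

# Wilson score interval by numerically inverting the score test:
# bounds are the p0 where |phat - p0| = z * sqrt(p0 (1 - p0) / n).
oracle_wilson <- function(successes, n, level = 0.95) {
  phat <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  g <- function(p0) (phat - p0)^2 - z^2 * p0 * (1 - p0) / n
  lo <- if (successes == 0) 0
        else uniroot(g, c(1e-12, phat * (1 - 1e-9)), tol = 1e-12)$root
  hi <- if (successes == n) 1
        else uniroot(g, c(max(phat, 1e-12) * (1 + 1e-9), 1 - 1e-12),
                     tol = 1e-12)$root
  100 * c(lo, hi)
}

# Pearson chi-square from first principles (expected counts).
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Small fully-specified cohort built in code.
tiny_cohort <- function(n = 10, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      id = sprintf("T%03d", seq_len(n)),
      age = sample(40:74, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      smoker = sample(c(TRUE, FALSE), n, replace = TRUE),
      sbp1 = runif(n, 95, 190), sbp2 = runif(n, 95, 190),
      dbp1 = runif(n, 60, 110), dbp2 = runif(n, 60, 110),
      height_cm = runif(n, 145, 175), weight_kg = runif(n, 40, 90),
      bmi = rep(NA_real_, n), glucose = runif(n, 4, 14),
      residence = sample(c("urban", "rural"), n, replace = TRUE),
      prior_cvd = rep(FALSE, n)
    )
  })
}

# Per-record recount of the distribution table.
oracle_distribution_counts <- function(scored, sex) {
  cats <- c("very_low", "low", "moderate", "high", "very_high")
  sub <- scored[scored$sex == sex, ]
  vapply(cats, function(cl) {
    sum(vapply(sub$risk_percent, function(r) {
      if (r < 5) cl == "very_low"
      else if (r < 10) cl == "low"
      else if (r < 20) cl == "moderate"
      else if (r < 30) cl == "high"
      else cl == "very_high"
    }, logical(1)))
  }, integer(1))
}

# Per-record recount of eligibility percentages for one stratum.
oracle_eligibility <- function(scored, stratum) {
  sub <- if (stratum == "total") scored
         else scored[scored$sex == c(men = "male", women = "female")[stratum], ]
  recount <- function(elig) 100 * sum(elig, na.rm = TRUE) / sum(!is.na(elig))
  c(A = recount(sub$risk_percent >= 20),
    B = recount(sub$risk_percent >= 20 | sub$severe_htn),
    C = recount(sub$htn))
}
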
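scored_fixture <- function(n = 40, seed = 21, chart = generate_chart_fixture()) {
  score_cohort(generate_cohort(generator_config(n = n, seed = seed)), chart)
}

test_that("distribution percentages recompute the published total column", {
  counts <- read.csv(chartrisk_example("risk_counts_bangladesh_2013.csv"))
  tab <- distribution_from_counts(setNames(counts$men, counts$category),
                                  setNames(counts$women, counts$category))
  expect_equal(attr(tab, "N"), c(total = 5977, men = 2708, women = 3269))
  expect_equal(round_half_up(tab$percent_total, 1), c(52.1, 33.0, 14.4, 0.5, 0.0))
  lt10 <- 100 * sum(tab$n_total[1:2]) / attr(tab, "N")[["total"]]
  expect_equal(round_half_up(lt10, 1), 85.1)
  # the very-high-risk row's sex comparison
  expect_equal(round(tab$p_value[5], 3), 0.272)
  # counts conservation within each stratum
  expect_equal(sum(tab$n_total), 5977)
  expect_equal(sum(tab$n_men), 2708)
  expect_equal(sum(tab$n_women), 3269)
  expect_equal(sum(tab$percent_total), 100)
})

test_that("distribution and flag tables equal brute-force recounts on small cohorts", {
  for (seed in c(3, 17, 29)) {
    sc <- scored_fixture(n = 50, seed = seed)
    tab <- risk_distribution(sc)
    expect_equal(tab$n_men, unname(oracle_distribution_counts(sc, "male")))
    expect_equal(tab$n_women, unname(oracle_distribution_counts(sc, "female")))
    expect_equal(tab$n_total, tab$n_men + tab$n_women)
    expect_equal(sum(tab$n_total), nrow(sc))
    # percent columns are 100 n / N
    N <- attr(tab, "N")
    expect_equal(tab$percent_total, 100 * tab$n_total / N[["total"]])

    fb <- flags_by_risk_group(sc, "htn")
    for (i in seq_len(nrow(fb))) {
      sel <- sc$risk_category == fb$category[i] & !is.na(sc$htn)
      expect_equal(fb$n_known[i], sum(sel))
      if (fb$n_known[i] > 0) {
        expect_equal(fb$percent[i], 100 * sum(sc$htn[sel]) / sum(sel))
      } else {
        expect_true(fb$empty[i] && is.na(fb$percent[i]))
      }
    }
  }
})

test_that("a cohort with universal hypertension shows 100% in every nonempty category", {
  co <- tiny_cohort(30)
  co$sbp1 <- co$sbp2 <- runif(30, 150, 190)  # all >= 140
  sc <- score_cohort(co, generate_chart_fixture())
  fb <- flags_by_risk_group(sc, "htn")
  expect_true(all(fb$percent[!fb$empty] == 100))
})

test_that("eligibility rules follow their union semantics per record", {
  chart <- generate_chart_fixture()
  # high risk and high BP: all three rules
  co <- tiny_cohort(2)
  co$age <- c(74, 55); co$smoker <- c(TRUE, FALSE)
  co$sbp1 <- co$sbp2 <- c(185, 165); co$dbp1 <- co$dbp2 <- c(95, 95)
  co$height_cm <- 160; co$weight_kg <- c(95, 60)  # BMI ~37, ~23
  sc <- score_cohort(co, chart)
  el <- treatment_eligibility(sc)
  expect_gte(sc$risk_percent[1], 20)
  expect_lt(sc$risk_percent[2], 20)
  expect_equal(unname(unlist(el$membership[1, c("rule_A", "rule_B", "rule_C")])),
               c(TRUE, TRUE, TRUE))
  # risk < 20 but BP 165/95: severe by SBP, so B and C only
  expect_equal(unname(unlist(el$membership[2, c("rule_A", "rule_B", "rule_C")])),
               c(FALSE, TRUE, TRUE))
})

test_that("eligibility summaries equal brute-force recounts and A is a subset of B", {
  for (seed in 4:9) {
    sc <- scored_fixture(n = 50, seed = seed)
    el <- treatment_eligibility(sc)
    expect_true(all(el$membership$rule_B[el$membership$rule_A], na.rm = TRUE))
    for (st in c("men", "women", "total")) {
      want <- oracle_eligibility(sc, st)
      got <- el$summary[el$summary$stratum == st, ]
      expect_equal(setNames(got$percent, got$rule), want,
                   info = paste("seed", seed, st))
    }
  }
})

test_that("when every high-risk record is hypertensive, B is a subset of C", {
  # construct the observed pattern: risk >= 20 only with raised BP
  co <- tiny_cohort(60, seed = 31)
  high_bp <- (co$sbp1 + co$sbp2) / 2 >= 140
  co$age[!high_bp] <- pmin(co$age[!high_bp], 54)  # keep low-BP records low-risk
  sc <- score_cohort(co, generate_chart_fixture())
  keep <- !is.na(sc$htn)
  if (any(sc$risk_percent >= 20)) {
    expect_true(all(sc$htn[sc$risk_percent >= 20]))
  }
  mem <- treatment_eligibility(sc)$membership
  expect_true(all(mem$rule_C[keep][mem$rule_B[keep]], na.rm = TRUE))
})

test_that("tables render to CSV with the expected shape", {
  sc <- scored_fixture(n = 50, seed = 2)
  dist_path <- tempfile(fileext = ".csv")
  write_table_csv(risk_distribution(sc), dist_path)
  dist <- read.csv(dist_path)
  expect_equal(nrow(dist), 5)
  expect_true(all(c("category", "n_total", "percent_total", "p_value") %in%
                    names(dist)))
  elig_path <- tempfile(fileext = ".csv")
  write_table_csv(treatment_eligibility(sc), elig_path)
  elig <- read.csv(elig_path)
  expect_equal(nrow(elig), 9)  # {men, women, total} x {A, B, C}
  expect_setequal(unique(elig$stratum), c("men", "women", "total"))
  expect_setequal(unique(elig$rule), c("A", "B", "C"))
})
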
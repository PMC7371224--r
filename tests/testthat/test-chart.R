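make_chart_csv <- function(cells, path = tempfile(fileext = ".csv")) {
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a complete chart loads; incomplete, duplicated or invalid charts are rejected", {
  chart <- generate_chart_fixture()
  expect_s3_class(chart, "risk_chart")
  expect_equal(nrow(chart), 700)

  path <- make_chart_csv(as.data.frame(chart))
  reloaded <- load_chart(path)
  expect_equal(as.data.frame(reloaded), as.data.frame(chart))

  # one row deleted: validation names the absent coordinate
  df <- as.data.frame(chart)
  dropped <- df[-137, ]
  err <- expect_error(as_risk_chart(dropped), class = "chartrisk_error")
  expect_match(conditionMessage(err), "missing 1 cell")
  expect_match(conditionMessage(err),
               chart_coord <- paste(df$sex[137], df$smoker[137],
                                    df$age_band[137], df$sbp_band[137],
                                    df$bmi_band[137], sep = "|"),
               fixed = TRUE)

  # duplicated row (conflicting value)
  dup <- rbind(df, transform(df[42, ], risk_percent = risk_percent + 1))
  expect_error(as_risk_chart(dup), class = "chartrisk_error")

  # risk outside [0, 100]
  bad <- df; bad$risk_percent[1] <- 101
  expect_error(as_risk_chart(bad), class = "chartrisk_error")
  bad$risk_percent[1] <- -0.5
  expect_error(as_risk_chart(bad), class = "chartrisk_error")
})

test_that("lookup reads the unique cell, deterministically, and flags unscorable ages", {
  chart <- generate_chart_fixture()
  # direct cell read: compare against a hand-picked cell of the table
  cell <- chart[chart$sex == "male" & chart$smoker == 1 &
                  chart$age_band == "60-64" & chart$sbp_band == "160-179" &
                  chart$bmi_band == "25-29", ]
  prof <- data.frame(age = 62, sex = "male", smoker = TRUE,
                     sbp = 165, bmi = 27)
  expect_equal(as.numeric(lookup_risk(prof, chart)), cell$risk_percent)

  # identical profiles give identical risks; no hidden state
  profs <- tiny_cohort(25)
  p2 <- data.frame(age = profs$age, sex = profs$sex, smoker = profs$smoker,
                   sbp = profs$sbp1, bmi = 22)
  expect_identical(lookup_risk(p2, chart), lookup_risk(p2, chart))

  # age off the chart: NA under exclude, top band under clamp
  old <- data.frame(age = 77, sex = "female", smoker = FALSE,
                    sbp = 120, bmi = 22)
  expect_true(is.na(lookup_risk(old, chart)))
  clamped <- lookup_risk(old, chart, age_policy = "clamp")
  expect_false(is.na(clamped))
  expect_true(attr(clamped, "clamped"))

  expect_error(lookup_risk(transform(prof, sbp = NA), chart),
               class = "chartrisk_error")
})

test_that("lookup agrees with brute-force rebinning on random profiles", {
  chart <- generate_chart_fixture()
  withr::with_seed(99, {
    n <- 10000
    profs <- data.frame(
      age = sample(40:74, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      smoker = sample(c(TRUE, FALSE), n, replace = TRUE),
      sbp = runif(n, 50, 300), bmi = runif(n, 10, 80)
    )
  })
  got <- as.numeric(lookup_risk(profs, chart))
  df <- as.data.frame(chart)
  key_df <- paste(df$sex, df$smoker, df$age_band, df$sbp_band, df$bmi_band)
  want <- vapply(seq_len(nrow(profs)), function(i) {
    k <- paste(profs$sex[i], as.integer(profs$smoker[i]),
               oracle_bin(profs$age[i], age_bands()),
               oracle_bin(profs$sbp[i], sbp_bands()),
               oracle_bin(profs$bmi[i], bmi_bands()))
    df$risk_percent[key_df == k]
  }, numeric(1))
  expect_equal(got, want)
  expect_equal(as.character(categorize_risk(got)),
               as.character(categorize_risk(want)))
})

test_that("on a monotone chart, risk is non-decreasing along every axis", {
  chart <- generate_chart_fixture()  # multiplicative increments >= 1
  df <- as.data.frame(chart)
  axes <- list(age_band = age_bands()$label, sbp_band = sbp_bands()$label,
               bmi_band = bmi_bands()$label, smoker = c(0, 1))
  for (axis in names(axes)) {
    ordered_levels <- axes[[axis]]
    others <- setdiff(c("sex", "smoker", "age_band", "sbp_band", "bmi_band"),
                      axis)
    grp <- interaction(df[others], drop = TRUE)
    for (g in levels(grp)) {
      sub <- df[grp == g, ]
      risk_along <- sub$risk_percent[match(ordered_levels, sub[[axis]])]
      expect_true(all(diff(risk_along) >= 0),
                  info = paste("axis", axis, "group", g))
    }
  }
})

test_that("chart fixtures are controllable: constant chart and very-high top cell", {
  flat <- generate_chart_fixture(base_risk = 1, age_mult = 1, sbp_mult = 1,
                                 bmi_mult = 1, smoke_mult = 1)
  expect_true(all(flat$risk_percent == 1))
  default <- generate_chart_fixture()
  top <- default[default$sex == "male" & default$smoker == 1 &
                   default$age_band == "70-74" & default$sbp_band == "ge180" &
                   default$bmi_band == "ge35", "risk_percent"]
  expect_equal(top, min(0.8 * 1.5^6 * 1.35^4 * 1.15^4 * 1.6, 100))
  expect_gt(top, 30)  # at least one very-high cell
  capped <- generate_chart_fixture(base_risk = 50, age_mult = 2)
  expect_true(all(capped$risk_percent <= 100))
})
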
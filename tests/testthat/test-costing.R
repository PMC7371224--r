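test_that("per-person annual costs follow price/100 x tablets x 365", {
  unit <- annual_cost_per_person(default_drug_prices())
  expect_equal(unname(unit["aspirin"]), 1.6425)
  expect_equal(unname(unit["enalapril"]), 8.687)
  expect_equal(unname(unit["hydrochlorothiazide"]), 3.0295)
  expect_equal(unname(unit["simvastatin"]), 15.549)
  free <- data.frame(drug = "x", price_per_100_tablets_usd = 0,
                     tablets_per_day = 1)
  expect_equal(unname(annual_cost_per_person(free)), 0)
  twice <- data.frame(drug = "x", price_per_100_tablets_usd = 1,
                      tablets_per_day = 2)
  expect_equal(unname(annual_cost_per_person(twice)), 7.3)
})

test_that("per-million headcounts scale and round half-up", {
  expect_equal(people_per_million(c(0.5, 22.1, 0)), c(5000L, 221000L, 0L))
  expect_equal(people_per_million(0.00005), 1L)  # 0.5 rounds up
  expect_error(people_per_million(-1), class = "chartrisk_error")
  expect_error(people_per_million(101), class = "chartrisk_error")
})

test_that("cost report is linear, additive over drugs, and internally consistent", {
  prices <- default_drug_prices()
  r1 <- cost_per_million(2.4, prices)
  r2 <- cost_per_million(4.8, prices)
  expect_equal(2 * r1$total_cost_usd, r2$total_cost_usd)  # p x 1e4 integral
  # total equals the sum of per-drug columns
  drug_cols <- grep("^cost_.*_usd$", names(r1), value = TRUE)
  expect_equal(sum(r1[drug_cols]), r1$total_cost_usd)
  # regimen total equals the sum over single-drug regimens
  singles <- vapply(seq_len(nrow(prices)), function(i) {
    cost_per_million(2.4, prices[i, , drop = FALSE])$total_cost_usd
  }, numeric(1))
  expect_equal(sum(singles), r1$total_cost_usd)
  expect_equal(cost_per_million(0)$total_cost_usd, 0)
})

test_that("the footnote simvastatin price and regimen scope are configurable", {
  foot <- default_drug_prices(simvastatin_footnote = TRUE)
  expect_equal(foot$price_per_100_tablets_usd[foot$drug == "simvastatin"], 4.29)
  bp_only <- default_drug_prices(antihypertensive_only = TRUE)
  expect_setequal(bp_only$drug, c("enalapril", "hydrochlorothiazide"))
  r <- cost_per_million(1, bp_only)
  expect_equal(r$total_cost_usd, 10000 * (8.687 + 3.0295))
})

test_that("population projection multiplies strata and conserves totals", {
  pop <- read_population(chartrisk_example("population_bangladesh_2013.csv"))
  prev <- read_prevalences(chartrisk_example("prevalence_bangladesh_2013.csv"))
  single <- prev[prev$approach == "single_risk" & prev$age_group != "all", ]
  proj <- project_population(pop, single)
  men4049 <- proj$persons_requiring_treatment[proj$sex == "male" &
                                                proj$age_group == "40-49"]
  expect_equal(men4049, 9210 * 1000 * 17.1 / 100)  # 1,574,910
  # totals are sums of their strata
  strat <- proj[proj$age_group != "all", ]
  tot <- proj[proj$age_group == "all", ]
  for (s in c("male", "female")) {
    expect_equal(tot$persons_requiring_treatment[tot$sex == s],
                 sum(strat$persons_requiring_treatment[strat$sex == s]))
  }
  expect_equal(tot$persons_requiring_treatment[tot$sex == "all"],
               sum(strat$persons_requiring_treatment))
  # linearity: halving prevalences halves projections
  half <- single; half$prevalence_percent <- half$prevalence_percent / 2
  proj_half <- project_population(pop, half)
  expect_equal(proj_half$persons_requiring_treatment,
               proj$persons_requiring_treatment / 2)
  # zero-population stratum projects zero
  pop0 <- pop; pop0$population_thousands[1] <- 0
  expect_equal(project_population(pop0, single)$persons_requiring_treatment[1], 0)
  # missing stratum prevalence is an error naming the stratum
  err <- expect_error(project_population(pop, single[-3, ]),
                      class = "chartrisk_error")
  expect_match(conditionMessage(err), "male 60-69")
})

test_that("strategy comparison reports differences and flags zero denominators", {
  a <- cost_per_million(24.6, stratum = "all")
  b <- cost_per_million(0.5, stratum = "all")
  cmp <- compare_approaches(a, b)
  expect_equal(cmp$ratio, 49.2)
  expect_equal(cmp$difference_usd, 7111368 - 144540)
  same <- compare_approaches(a, a)
  expect_equal(same$ratio, 1)
  expect_equal(same$difference_usd, 0)
  zero <- compare_approaches(a, cost_per_million(0, stratum = "all"))
  expect_true(is.na(zero$ratio) && zero$ratio_undefined)
})

test_that("price tables validate on read", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(drug = c("a", "a"), price_per_100_tablets_usd = 1,
                       tablets_per_day = 1), path, row.names = FALSE)
  expect_error(read_drug_prices(path), "duplicated", class = "chartrisk_error")
  write.csv(data.frame(drug = "a", price_per_100_tablets_usd = -1,
                       tablets_per_day = 1), path, row.names = FALSE)
  expect_error(read_drug_prices(path), class = "chartrisk_error")
  bundled <- read_drug_prices(chartrisk_example("drug_prices_bangladesh_2013.csv"))
  expect_equal(bundled$price_per_100_tablets_usd,
               default_drug_prices()$price_per_100_tablets_usd)
})
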
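# Annual drug-cost projection per million adults aged >= 40, and
# absolute population projections, for comparing treatment strategies.

#' Default generic drug price table
#'
#' Lowest-available generic prices (US$ per 100 tablets, one tablet per
#' day) for the four-drug preventive regimen: aspirin 0.45, enalapril
#' 2.38, hydrochlorothiazide 0.83, simvastatin 4.26.  The published
#' Bangladeshi costing scenario that this table reproduces prints a
#' simvastatin catalogue price of 4.29 in its footnote, but every one of
#' its cost cells implies 4.26 (annual per-person cost 15.549 =
#' 4.26/100 x 365); the implied price is therefore the default and the
#' footnote value is available via `simvastatin_footnote = TRUE`.
#'
#' @param simvastatin_footnote Use the 4.29 catalogue price instead of
#'   the implied 4.26.
#' @param antihypertensive_only Drop aspirin and simvastatin, leaving the
#'   blood-pressure drugs only.
#' @return Data frame with columns `drug`, `price_per_100_tablets_usd`,
#'   `tablets_per_day`.
#' @export
default_drug_prices <- function(simvastatin_footnote = FALSE,
                                antihypertensive_only = FALSE) {
  prices <- data.frame(
    drug = c("aspirin", "enalapril", "hydrochlorothiazide", "simvastatin"),
    price_per_100_tablets_usd = c(0.45, 2.38, 0.83,
                                  if (simvastatin_footnote) 4.29 else 4.26),
    tablets_per_day = 1
  )
  if (antihypertensive_only) {
    prices <- prices[prices$drug %in% c("enalapril", "hydrochlorothiazide"), ]
    rownames(prices) <- NULL
  }
  prices
}

#' Read a drug price table from CSV
#'
#' Header `drug,price_per_100_tablets_usd,tablets_per_day`; drug names
#' must be unique, prices >= 0 and tablets per day > 0.
#'
#' @param path Path to the price CSV.
#' @return Validated price data frame.
#' @export
read_drug_prices <- function(path) {
  if (!file.exists(path)) cr_abort(paste("price file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "price_per_100_tablets_usd", "tablets_per_day")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cr_abort(paste("price file missing column(s):", paste(miss, collapse = ", ")))
  }
  if (anyNA(df$price_per_100_tablets_usd) ||
      any(df$price_per_100_tablets_usd < 0)) {
    cr_abort("drug prices must be non-negative")
  }
  if (anyNA(df$tablets_per_day) || any(df$tablets_per_day <= 0)) {
    cr_abort("tablets_per_day must be positive")
  }
  if (anyDuplicated(df$drug)) cr_abort("duplicated drug names in price table")
  df[need]
}

#' Annual per-person cost of one drug
#'
#' `price_per_100_tablets / 100 x tablets_per_day x 365`.
#'
#' @param prices A price data frame ([default_drug_prices()] layout).
#' @return Named numeric vector of US$/person/year, one entry per drug.
#' @examples
#' annual_cost_per_person(default_drug_prices())  # aspirin 1.6425, ...
#' @export
annual_cost_per_person <- function(prices) {
  stats::setNames(prices$price_per_100_tablets_usd / 100 *
                    prices$tablets_per_day * 365,
                  prices$drug)
}

#' People requiring treatment per million population
#'
#' @param prevalence_percent Numeric vector of prevalences in \[0, 100\].
#' @return Integer count(s) per one million adults aged >= 40
#'   (prevalence x 10 000, rounded half-up).
#' @examples
#' people_per_million(0.5)   # 5000
#' people_per_million(22.1)  # 221000
#' @export
people_per_million <- function(prevalence_percent) {
  if (anyNA(prevalence_percent) || any(prevalence_percent < 0) ||
      any(prevalence_percent > 100)) {
    cr_abort("prevalence_percent must lie in [0, 100]")
  }
  as.integer(round_half_up(prevalence_percent * 1e4))
}

#' Annual drug cost per million adults aged 40 and over
#'
#' For each prevalence, the number of people per million requiring
#' treatment and the annual cost of keeping each of them on the regimen:
#' per-drug cost = people x annual per-person cost, total = sum over
#' drugs.
#'
#' @param prevalence_percent Numeric vector of prevalences (percent).
#' @param prices Price data frame; default [default_drug_prices()].
#' @param stratum Optional character vector labelling each prevalence.
#' @return Data frame of class `cost_report`: `stratum`,
#'   `prevalence_percent`, `people_per_million`, one `cost_<drug>_usd`
#'   column per drug, `total_cost_usd`.
#' @examples
#' cost_per_million(0.5)$total_cost_usd    # 144540
#' cost_per_million(24.6)$total_cost_usd   # 7111368
#' @export
cost_per_million <- function(prevalence_percent,
                             prices = default_drug_prices(),
                             stratum = NULL) {
  people <- people_per_million(prevalence_percent)
  unit <- annual_cost_per_person(prices)
  per_drug <- outer(people, unit)
  colnames(per_drug) <- paste0("cost_", names(unit), "_usd")
  out <- data.frame(
    stratum = if (is.null(stratum)) as.character(seq_along(people))
              else as.character(stratum),
    prevalence_percent = prevalence_percent,
    people_per_million = people
  )
  out <- cbind(out, as.data.frame(per_drug))
  out$total_cost_usd <- rowSums(per_drug)
  attr(out, "drugs") <- prices$drug
  class(out) <- c("cost_report", "data.frame")
  out
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Annual drug cost per million adults aged >= 40 (US$)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %5.1f%% -> %7d people, total %14s\n",
                x$stratum[i], x$prevalence_percent[i],
                x$people_per_million[i],
                formatC(x$total_cost_usd[i], format = "f", digits = 1,
                        big.mark = " ")))
  }
  invisible(x)
}

#' Read a population stratum table from CSV
#'
#' Header `sex,age_group,population_thousands`; age groups `40-49`,
#' `50-59`, `60-69`, `ge70`.
#'
#' @param path Path to the population CSV.
#' @return Validated data frame.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) cr_abort(paste("population file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_group", "population_thousands")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cr_abort(paste("population file missing column(s):",
                   paste(miss, collapse = ", ")))
  }
  if (anyNA(df$population_thousands) || any(df$population_thousands < 0)) {
    cr_abort("population_thousands must be non-negative")
  }
  df[need]
}

#' Project absolute numbers requiring treatment
#'
#' Multiplies each population stratum by its prevalence:
#' `population_thousands x 1000 x prevalence/100`, then appends per-sex
#' and overall totals (sums of the stratum projections, with the implied
#' aggregate prevalence).
#'
#' @param population Data frame from [read_population()].
#' @param prevalence Data frame with `sex`, `age_group`,
#'   `prevalence_percent`; every population stratum must be covered.
#' @return Data frame with `sex`, `age_group`, `population_thousands`,
#'   `prevalence_percent`, `persons_requiring_treatment`; total rows have
#'   `age_group == "all"` and `sex` of `male`/`female`/`all`.
#' @export
project_population <- function(population, prevalence) {
  key_p <- paste(population$sex, population$age_group)
  key_r <- paste(prevalence$sex, prevalence$age_group)
  idx <- match(key_p, key_r)
  if (anyNA(idx)) {
    cr_abort(sprintf("no prevalence supplied for stratum(s): %s",
                     paste(key_p[is.na(idx)], collapse = ", ")))
  }
  out <- population
  out$prevalence_percent <- prevalence$prevalence_percent[idx]
  out$persons_requiring_treatment <-
    out$population_thousands * 1000 * out$prevalence_percent / 100
  totals <- function(rows, sex_label) {
    pop <- sum(rows$population_thousands)
    per <- sum(rows$persons_requiring_treatment)
    data.frame(sex = sex_label, age_group = "all",
               population_thousands = pop,
               prevalence_percent = if (pop > 0) 100 * per / (pop * 1000)
                                    else NA_real_,
               persons_requiring_treatment = per)
  }
  tot <- do.call(rbind, c(
    lapply(unique(out$sex), function(s) totals(out[out$sex == s, ], s)),
    list(totals(out, "all"))
  ))
  rbind(out, tot)
}

#' Compare the cost of two treatment strategies
#'
#' Matches two cost reports by stratum and reports the absolute
#' difference and the cost ratio (first over second).  A zero-cost
#' denominator leaves the ratio undefined (`NA`, flagged).
#'
#' @param report_a,report_b `cost_report` objects over the same strata
#'   (e.g. single-risk-factor vs total-risk approach).
#' @return Data frame of class `approach_comparison` with `stratum`,
#'   `total_a_usd`, `total_b_usd`, `difference_usd`, `ratio`,
#'   `ratio_undefined`.
#' @examples
#' a <- cost_per_million(24.6, stratum = "total")
#' b <- cost_per_million(0.5, stratum = "total")
#' compare_approaches(a, b)$ratio  # 49.2
#' @export
compare_approaches <- function(report_a, report_b) {
  idx <- match(report_a$stratum, report_b$stratum)
  if (anyNA(idx)) {
    cr_abort(sprintf("strata not present in both reports: %s",
                     paste(report_a$stratum[is.na(idx)], collapse = ", ")))
  }
  b <- report_b[idx, ]
  out <- data.frame(
    stratum = report_a$stratum,
    total_a_usd = report_a$total_cost_usd,
    total_b_usd = b$total_cost_usd,
    difference_usd = report_a$total_cost_usd - b$total_cost_usd
  )
  out$ratio <- ifelse(out$total_b_usd == 0, NA_real_,
                      out$total_a_usd / out$total_b_usd)
  out$ratio_undefined <- out$total_b_usd == 0
  class(out) <- c("approach_comparison", "data.frame")
  out
}
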
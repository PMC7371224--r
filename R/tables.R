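# Stratified risk-distribution, flag and treatment-eligibility tables.

#' Risk-category distribution from per-sex counts
#'
#' Core tabulation used by [risk_distribution()]: takes category counts
#' for men and women and produces per-category n, percent, confidence
#' interval (per stratum: men, women, total) and the per-category
#' chi-square sex-comparison p-value.  Exposed so that published count
#' tables can be re-summarised without record-level data.
#'
#' @param men,women Named integer vectors of counts, names being the five
#'   risk-category levels (missing categories count 0).
#' @param ci_method,level Passed to [proportion_ci()].
#' @return Data frame of class `distribution_table`: one row per category
#'   with columns `category`, then `n`, `percent`, `ci_low`, `ci_high`
#'   for each of `total`, `men`, `women` (suffixing), and `p_value`.
#'   Stratum sizes are attached as attribute `"N"`.
#' @export
distribution_from_counts <- function(men, women, ci_method = "wilson",
                                     level = 0.95) {
  counts <- function(x) {
    out <- stats::setNames(integer(length(RISK_CATEGORY_LEVELS)),
                           RISK_CATEGORY_LEVELS)
    out[names(x)] <- as.integer(x)
    out
  }
  men <- counts(men); women <- counts(women)
  total <- men + women
  N <- c(total = sum(total), men = sum(men), women = sum(women))

  stratum_cols <- function(n_vec, N_str, suffix) {
    est <- lapply(n_vec, function(k) {
      if (N_str == 0) {
        list(percent = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else proportion_ci(k, N_str, level, ci_method)
    })
    out <- data.frame(
      n = unname(n_vec),
      percent = vapply(est, function(e) e$percent, 0),
      ci_low = vapply(est, function(e) e$ci_low, 0),
      ci_high = vapply(est, function(e) e$ci_high, 0)
    )
    names(out) <- paste(names(out), suffix, sep = "_")
    out
  }
  tab <- cbind(
    data.frame(category = factor(RISK_CATEGORY_LEVELS,
                                 levels = RISK_CATEGORY_LEVELS)),
    stratum_cols(total, N[["total"]], "total"),
    stratum_cols(men, N[["men"]], "men"),
    stratum_cols(women, N[["women"]], "women")
  )
  tab$p_value <- vapply(seq_along(men), function(i) {
    if (N[["men"]] == 0 || N[["women"]] == 0) return(NA_real_)
    as.numeric(sex_comparison_test(men[i], N[["men"]], women[i], N[["women"]]))
  }, 0)
  attr(tab, "N") <- N
  attr(tab, "ci_method") <- ci_method
  class(tab) <- c("distribution_table", "data.frame")
  tab
}

#' Risk-category distribution of a scored cohort
#'
#' Tabulates the five risk categories overall and by sex, with confidence
#' intervals and per-category chi-square sex comparisons.
#'
#' @param scored A `scored_cohort` from [score_cohort()].
#' @param ci_method,level Passed to [proportion_ci()].
#' @return A `distribution_table`; see [distribution_from_counts()].
#' @export
risk_distribution <- function(scored, ci_method = "wilson", level = 0.95) {
  if (!nrow(scored)) cr_abort("scored cohort is empty")
  tab_sex <- function(s) {
    x <- scored$risk_category[scored$sex == s]
    stats::setNames(as.integer(table(x)), levels(x))
  }
  distribution_from_counts(tab_sex("male"), tab_sex("female"),
                           ci_method, level)
}

#' @export
print.distribution_table <- function(x, digits = 1, ...) {
  N <- attr(x, "N")
  cat(sprintf("10-year CVD risk distribution (total n=%d; men %d, women %d)\n",
              N[["total"]], N[["men"]], N[["women"]]))
  fmt <- function(p) formatC(round_half_up(p, digits), format = "f",
                             digits = digits)
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s total %4d (%s%%, CI %s)  men %4d (%s%%)  women %4d (%s%%)  p=%s\n",
                x$category[i],
                x$n_total[i], fmt(x$percent_total[i]),
                format_ci(x$ci_low_total[i], x$ci_high_total[i], digits),
                x$n_men[i], fmt(x$percent_men[i]),
                x$n_women[i], fmt(x$percent_women[i]),
                ifelse(is.na(x$p_value[i]), "NA",
                       format.pval(x$p_value[i], digits = 3, eps = 0.001))))
  }
  invisible(x)
}

#' Flag prevalence by risk category
#'
#' For each risk category, the percentage of records with the flag `TRUE`
#' among records where the flag is non-missing.
#'
#' @param scored A `scored_cohort`.
#' @param flag One of `"htn"`, `"severe_htn"`, `"hyperglycaemia"`,
#'   `"overweight_obesity"`.
#' @return Data frame with `category`, `n_true`, `n_known`, `percent`
#'   (`NA`, flagged by `empty`, where a category has no known values).
#' @export
flags_by_risk_group <- function(scored, flag = c("htn", "severe_htn",
                                                 "hyperglycaemia",
                                                 "overweight_obesity")) {
  flag <- match.arg(flag)
  f <- scored[[flag]]
  cat <- scored$risk_category
  out <- do.call(rbind, lapply(RISK_CATEGORY_LEVELS, function(cl) {
    known <- !is.na(f) & cat == cl
    data.frame(category = cl, n_true = sum(f[known]), n_known = sum(known))
  }))
  out$percent <- ifelse(out$n_known > 0, 100 * out$n_true / out$n_known,
                        NA_real_)
  out$empty <- out$n_known == 0
  out$category <- factor(out$category, levels = RISK_CATEGORY_LEVELS)
  attr(out, "flag") <- flag
  out
}

#' Treatment eligibility under competing guideline rules
#'
#' Three rules are evaluated per record:
#' \describe{
#'   \item{A (total risk alone)}{10-year risk >= 20\%.}
#'   \item{B (total risk extended)}{risk >= 20\% or severe hypertension
#'     (BP >= 160/100).}
#'   \item{C (single risk factor)}{hypertension (BP >= 140/90).}
#' }
#' Rule A membership is always a subset of rule B.  Records whose inputs
#' leave a rule undetermined are counted separately as unknown, never as
#' ineligible.
#'
#' @param scored A `scored_cohort`.
#' @return List of class `eligibility_table`: `membership` (per-record
#'   logical columns `rule_A`, `rule_B`, `rule_C` alongside `id` and
#'   `sex`) and `summary` (rows men/women/total x per-rule `n_eligible`,
#'   `n_known`, `n_unknown`, `percent` of known).
#' @export
treatment_eligibility <- function(scored) {
  if (!nrow(scored)) cr_abort("scored cohort is empty")
  mem <- data.frame(
    id = scored$id, sex = scored$sex,
    rule_A = scored$risk_percent >= 20,
    rule_B = (scored$risk_percent >= 20) | scored$severe_htn,
    rule_C = scored$htn
  )
  strata <- list(men = mem$sex == "male", women = mem$sex == "female",
                 total = rep(TRUE, nrow(mem)))
  rows <- list()
  for (s in names(strata)) {
    for (r in c("rule_A", "rule_B", "rule_C")) {
      v <- mem[[r]][strata[[s]]]
      known <- sum(!is.na(v))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, rule = sub("rule_", "", r),
        n_eligible = sum(v, na.rm = TRUE), n_known = known,
        n_unknown = sum(is.na(v)),
        percent = if (known > 0) 100 * sum(v, na.rm = TRUE) / known
                  else NA_real_
      )
    }
  }
  out <- list(membership = mem, summary = do.call(rbind, rows))
  class(out) <- "eligibility_table"
  out
}

#' @export
print.eligibility_table <- function(x, digits = 1, ...) {
  cat("Treatment eligibility (% of records with known status)\n")
  s <- x$summary
  for (st in c("men", "women", "total")) {
    row <- s[s$stratum == st, ]
    cat(sprintf("  %-6s A %5s%%   B %5s%%   C %5s%%\n", st,
                formatC(round_half_up(row$percent[row$rule == "A"], digits),
                        format = "f", digits = digits),
                formatC(round_half_up(row$percent[row$rule == "B"], digits),
                        format = "f", digits = digits),
                formatC(round_half_up(row$percent[row$rule == "C"], digits),
                        format = "f", digits = digits)))
  }
  invisible(x)
}

#' Write an analysis table to CSV
#'
#' Flat CSV rendering of the objects produced by [risk_distribution()],
#' [treatment_eligibility()] (its summary), [flags_by_risk_group()],
#' [cost_per_million()] and [compare_approaches()].
#'
#' @param x The table object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  df <- if (inherits(x, "eligibility_table")) x$summary else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
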
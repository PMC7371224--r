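# Proportion confidence intervals and the 2x2 sex-comparison chi-square.

#' Round half away from zero
#'
#' Survey tables round 0.45 up to 0.5; base `round()` rounds to even.
#' Binary representation error is absorbed before flooring, so a value
#' stored as 520.4999...94 tenths still rounds up to 52.1.
#'
#' @param x Numeric vector (non-negative in all uses here).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.485 * 100 / 100, 1)  # 0.5
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  y <- round(abs(x) * p, 8)  # absorb representation error before the floor
  sign(x) * floor(y + 0.5) / p
}

#' Confidence interval for a proportion
#'
#' Wilson score interval (default) or Wald normal-approximation interval,
#' on the percent scale, clipped to \[0, 100\].
#'
#' @param successes Integer count of events.
#' @param n Integer denominator, >= 1.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"wilson"` or `"wald"`.
#' @return List of class `proportion_estimate` with `successes`, `n`,
#'   `percent`, `ci_low`, `ci_high`, `method`, `level`.
#' @examples
#' proportion_ci(29, 5977)                   # Wilson
#' proportion_ci(29, 5977, method = "wald")  # prints the same to 1 decimal
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (length(n) != 1 || is.na(n) || n < 1) cr_abort("n must be a positive integer")
  if (length(level) != 1 || level <= 0 || level >= 1) {
    cr_abort("level must be in (0, 1)")
  }
  if (is.na(successes) || successes < 0 || successes > n) {
    cr_abort("successes must lie in [0, n]")
  }
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  out <- list(successes = successes, n = n,
              percent = 100 * p,
              ci_low = max(0, 100 * lo),
              ci_high = min(100, 100 * hi),
              method = method, level = level)
  class(out) <- "proportion_estimate"
  out
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %s, %s)\n",
              x$successes, x$n, round_half_up(x$percent, 1),
              round(100 * x$level), format_ci(x$ci_low, x$ci_high), x$method))
  invisible(x)
}

#' Format a percent confidence interval the way survey tables print it
#'
#' @param ci_low,ci_high Bounds on the percent scale.
#' @param digits Decimal places (half-up rounding).
#' @return A string such as `"0.3 to 0.7"`.
#' @export
format_ci <- function(ci_low, ci_high, digits = 1) {
  paste0(formatC(round_half_up(ci_low, digits), format = "f", digits = digits),
         " to ",
         formatC(round_half_up(ci_high, digits), format = "f", digits = digits))
}

#' Chi-square test comparing one category's prevalence between sexes
#'
#' Pearson chi-square on the 2x2 table {in/out of category} x {men/women},
#' 1 degree of freedom, no continuity correction.  A zero margin (for
#' example a category empty in both sexes) leaves the statistic undefined
#' and returns `NA` flagged via the `"undefined"` attribute.
#'
#' @param in_category_men,in_category_women Counts in the category.
#' @param men_n,women_n Stratum totals (>= 1).
#' @return P-value (numeric scalar, `NA` if undefined) with attributes
#'   `"statistic"` (the chi-square) and `"undefined"`.
#' @examples
#' sex_comparison_test(1, 2708, 0, 3269)  # ~0.272
#' @export
sex_comparison_test <- function(in_category_men, men_n,
                                in_category_women, women_n) {
  counts <- c(in_category_men, men_n, in_category_women, women_n)
  if (anyNA(counts) || any(counts < 0) || men_n < 1 || women_n < 1 ||
      in_category_men > men_n || in_category_women > women_n) {
    cr_abort("invalid 2x2 counts")
  }
  tab <- matrix(c(in_category_men, men_n - in_category_men,
                  in_category_women, women_n - in_category_women),
                nrow = 2,
                dimnames = list(c("in", "out"), c("men", "women")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- NA_real_
    attr(out, "statistic") <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- unname(ct$p.value)
  attr(out, "statistic") <- unname(ct$statistic)
  attr(out, "undefined") <- FALSE
  out
}
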
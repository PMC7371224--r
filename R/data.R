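# Bundled example data: the published Bangladeshi survey scenario
# (2013, adults aged >= 40) used throughout the examples and the
# acceptance checks.

#' Paths to bundled example data
#'
#' The package ships small plain-text inputs for the Bangladeshi
#' costing scenario:
#' \describe{
#'   \item{`drug_prices_bangladesh_2013.csv`}{Lowest generic prices per
#'     100 tablets (see [default_drug_prices()]).}
#'   \item{`population_bangladesh_2013.csv`}{Census-projected population
#'     (thousands) by sex and age group.}
#'   \item{`prevalence_bangladesh_2013.csv`}{Published percentage of the
#'     population aged >= 40 requiring medication, by strategy
#'     (`total_risk`: 10-year risk >= 20%; `single_risk`: BP >= 140/90),
#'     sex and age group.}
#'   \item{`risk_counts_bangladesh_2013.csv`}{Published per-sex counts of
#'     scorable participants in each risk category (n = 5977).}
#' }
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' chartrisk_example()
#' read_drug_prices(chartrisk_example("drug_prices_bangladesh_2013.csv"))
#' @export
chartrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "chartrisk"))
  } else {
    path <- system.file("extdata", file, package = "chartrisk")
    if (path == "") cr_abort(paste("no bundled file named", file))
    path
  }
}

#' Read a prevalence table from CSV
#'
#' Header `approach,sex,age_group,prevalence_percent`; used with
#' [cost_per_million()] and [project_population()].
#'
#' @param path Path to the prevalence CSV.
#' @return Validated data frame.
#' @export
read_prevalences <- function(path) {
  if (!file.exists(path)) cr_abort(paste("prevalence file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("approach", "sex", "age_group", "prevalence_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cr_abort(paste("prevalence file missing column(s):",
                   paste(miss, collapse = ", ")))
  }
  if (anyNA(df$prevalence_percent) || any(df$prevalence_percent < 0) ||
      any(df$prevalence_percent > 100)) {
    cr_abort("prevalence_percent must lie in [0, 100]")
  }
  df[need]
}
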
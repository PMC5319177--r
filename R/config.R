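#' Study configuration
#'
#' Key dates and constants that define the analysis. Defaults correspond to
#' the evaluated program: pharmacy data available 2012-11-04 through
#' 2014-06-26, observation period starting 2013-07-01, and the weekly SMS
#' program launching 2013-09-09. All day intervals are closed on both ends;
#' a d-day prescription issued on day t covers days t through t+d-1.
#'
#' @param data_start First day of pharmacy data availability.
#' @param data_end Last day of pharmacy data availability (right-censoring
#'   date for patients who do not transfer out).
#' @param obs_start First day of the observation period.
#' @param program_start Launch date of the SMS program. The launch day itself
#'   is labeled `during_program`; the pre-program period is
#'   `[obs_start, program_start - 1]`.
#' @param carryover_cap_days Maximum number of remaining coverage days that
#'   may be carried over into a new same-regimen prescription (clinic
#'   policy; default 30).
#' @param adult_age_years Minimum age, in years at `data_start`, for cohort
#'   inclusion.
#' @param elimination_p Retention threshold for stepwise backward
#'   elimination of candidate covariates.
#' @param days_per_year Days per year used when translating the program
#'   effect odds ratio into days of coverage.
#'
#' @return An object of class `study_config` (a named list of validated
#'   values).
#' @examples
#' cfg <- study_config()
#' cfg$carryover_cap_days
#' @export
study_config <- function(data_start = "2012-11-04",
                         data_end = "2014-06-26",
                         obs_start = "2013-07-01",
                         program_start = "2013-09-09",
                         carryover_cap_days = 30L,
                         adult_age_years = 18L,
                         elimination_p = 0.25,
                         days_per_year = 365.25) {
  cfg <- list(
    data_start = as.Date(data_start),
    data_end = as.Date(data_end),
    obs_start = as.Date(obs_start),
    program_start = as.Date(program_start),
    carryover_cap_days = as.integer(carryover_cap_days),
    adult_age_years = as.integer(adult_age_years),
    elimination_p = as.numeric(elimination_p),
    days_per_year = as.numeric(days_per_year)
  )
  if (anyNA(cfg[1:4], recursive = TRUE)) {
    stop("study_config: all dates must parse as ISO-8601 (YYYY-MM-DD)")
  }
  if (!(cfg$data_start < cfg$obs_start &&
        cfg$obs_start < cfg$program_start &&
        cfg$program_start < cfg$data_end)) {
    stop("study_config: requires data_start < obs_start < program_start < data_end")
  }
  if (cfg$carryover_cap_days < 0) stop("study_config: carryover_cap_days must be >= 0")
  if (cfg$elimination_p <= 0 || cfg$elimination_p >= 1) {
    stop("study_config: elimination_p must lie in (0, 1)")
  }
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Any keys absent from the file fall back to the `study_config()` defaults.
#'
#' @param path Path to a YAML file whose keys match `study_config()`
#'   arguments.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown study_config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, vals)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  pharmacy data:    %s .. %s\n", x$data_start, x$data_end))
  cat(sprintf("  observation from: %s\n", x$obs_start))
  cat(sprintf("  program start:    %s\n", x$program_start))
  cat(sprintf("  carryover cap:    %d days\n", x$carryover_cap_days))
  cat(sprintf("  adult age:        %d years\n", x$adult_age_years))
  cat(sprintf("  elimination P:    %.2f\n", x$elimination_p))
  invisible(x)
}
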
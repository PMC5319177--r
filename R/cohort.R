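# Cohort construction: inclusion criteria, intention-to-treat exposure
# groups, mean substitution for missing covariates, baseline descriptives.

EXCLUSION_REASONS <- c("under_age", "no_rx_in_observation",
                       "not_enrolled_before", "delayed_phone_capture",
                       "no_observation_time")

#' Exclusion tally
#'
#' Screening arithmetic for cohort construction. The number included is
#' always the number screened minus the five exclusion counts, and the
#' constructor enforces that conservation.
#'
#' @param total_screened Number of patients screened.
#' @param under_age Excluded: younger than the adult age at the reference
#'   date.
#' @param no_rx_in_observation Excluded: no ART prescription issued during
#'   the observation period.
#' @param not_enrolled_before Excluded: enrolled at the clinic after the
#'   observation period began.
#' @param delayed_phone_capture Excluded: phone number captured into the
#'   program only after the observation period began.
#' @param no_observation_time Excluded: no observable person-time (e.g.
#'   transferred out before the end of the first prescription).
#' @return An object of class `exclusion_tally` with the counts and the
#'   derived `included`.
#' @examples
#' exclusion_tally(2920, 458, 33, 160, 1, 13)$included
#' @export
exclusion_tally <- function(total_screened, under_age = 0L,
                            no_rx_in_observation = 0L,
                            not_enrolled_before = 0L,
                            delayed_phone_capture = 0L,
                            no_observation_time = 0L) {
  counts <- c(total_screened = total_screened, under_age = under_age,
              no_rx_in_observation = no_rx_in_observation,
              not_enrolled_before = not_enrolled_before,
              delayed_phone_capture = delayed_phone_capture,
              no_observation_time = no_observation_time)
  if (any(counts < 0)) stop("exclusion_tally: counts must be non-negative")
  tl <- as.list(as.integer(counts))
  names(tl) <- names(counts)
  tl$included <- tl$total_screened - sum(unlist(tl[EXCLUSION_REASONS]))
  if (tl$included < 0) stop("exclusion_tally: exclusions exceed total screened")
  class(tl) <- "exclusion_tally"
  tl
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Screened: %d\n", x$total_screened))
  lab <- c(under_age = "Under adult age",
           no_rx_in_observation = "No ART prescription in observation period",
           not_enrolled_before = "Not enrolled before observation period",
           delayed_phone_capture = "Delayed phone-number capture",
           no_observation_time = "No observation time")
  for (r in EXCLUSION_REASONS) {
    cat(sprintf("  - %-42s %d\n", lab[[r]], x[[r]]))
  }
  cat(sprintf("Included: %d\n", x$included))
  invisible(x)
}

#' @export
as.data.frame.exclusion_tally <- function(x, ...) {
  data.frame(reason = c("total_screened", EXCLUSION_REASONS, "included"),
             n = unlist(x, use.names = FALSE), stringsAsFactors = FALSE)
}

age_at <- function(birth_date, ref) as.numeric(ref - birth_date) / 365.25

assign_group <- function(phone_status, phone_capture_date, obs_start) {
  if (phone_status == "available" && !is.na(phone_capture_date) &&
      phone_capture_date < obs_start) return("Exposed")
  if (phone_status == "absent") return("Unexposed")
  "Unknown"
}

#' Pre-program coverage proportion of one coverage series
#'
#' Covered days divided by total days over the series restricted to the
#' pre-program period; `NA` when the patient has no pre-program
#' observation time.
#'
#' @param coverage A `daily_coverage` series.
#' @return A proportion in `[0, 1]`, or `NA`.
#' @export
pre_program_coverage <- function(coverage) {
  pre <- coverage$period == "pre_program"
  if (!any(pre)) return(NA_real_)
  mean(coverage$covered[pre])
}

#' Build the analysis cohort
#'
#' Applies the inclusion criteria in a fixed order — age below the adult
#' threshold; no ART prescription issued in the observation period;
#' enrollment after the observation period start; phone number captured on
#' or after the observation period start; no observable person-time — with
#' each excluded patient counted once under the first matching reason.
#' Included patients are assigned an intention-to-treat exposure group from
#' their phone fields alone (`Exposed` when a number was captured before
#' the observation period, `Unexposed` when the chart showed no number,
#' `Unknown` when the chart was unavailable): opt-out and delivery failure
#' are disregarded. Each member gets an observation window, a day-level
#' coverage series, pre-program coverage, and patient-level covariates.
#'
#' @param patients,prescriptions Validated tables from [read_tables()] or
#'   [simulate_clinic()].
#' @param config A [study_config()].
#' @return An object of class `cohort`: a list with `members` (one row per
#'   included patient), `coverage` (named list of `daily_coverage` series),
#'   `tally` (an [exclusion_tally()]), `excluded` (patient ids and
#'   reasons), and the `config`.
#' @export
build_cohort <- function(patients, prescriptions, config = study_config()) {
  rx_split <- split(prescriptions, prescriptions$patient_id)
  counts <- stats::setNames(integer(length(EXCLUSION_REASONS)), EXCLUSION_REASONS)
  excluded <- list()
  members <- list()
  coverage <- list()

  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    pid <- p$patient_id
    rx_all <- rx_split[[pid]]
    if (is.null(rx_all)) rx_all <- prescriptions[0L, , drop = FALSE]
    rx_all <- rx_all[order(rx_all$issue_date), , drop = FALSE]
    rx <- dedup_prescriptions(rx_all)$kept

    age <- if (is.na(p$birth_date)) NA_real_ else age_at(p$birth_date, config$data_start)
    in_obs <- nrow(rx) > 0L && any(rx$issue_date >= config$obs_start &
                                     rx$issue_date <= config$data_end)
    window <- observation_window(p, rx, config)

    reason <- if (!is.na(age) && age < config$adult_age_years) {
      "under_age"
    } else if (!in_obs) {
      "no_rx_in_observation"
    } else if (p$enrollment_date > config$obs_start) {
      "not_enrolled_before"
    } else if (p$phone_status == "available" &&
               p$phone_capture_date >= config$obs_start) {
      "delayed_phone_capture"
    } else if (inherits(window, "no_obs_window")) {
      "no_observation_time"
    } else NA_character_

    if (!is.na(reason)) {
      counts[[reason]] <- counts[[reason]] + 1L
      excluded[[length(excluded) + 1L]] <-
        data.frame(patient_id = pid, reason = reason, stringsAsFactors = FALSE)
      next
    }

    cov <- daily_coverage(rx, window, config)
    coverage[[pid]] <- cov
    female <- if (is.na(p$gender)) NA_real_ else as.numeric(p$gender == "female")
    members[[length(members) + 1L]] <- data.frame(
      patient_id = pid,
      group = assign_group(p$phone_status, p$phone_capture_date, config$obs_start),
      window_start = window$start,
      window_end = window$end,
      has_pre_program_time = window$has_pre_program_time,
      age_years = age,
      female = female,
      art_start_date = p$art_start_date,
      transfer_out_date = p$transfer_out_date,
      pre_program_coverage = pre_program_coverage(cov),
      missing_any = as.numeric(is.na(age) | is.na(female)),
      rx_len_first_obs = cov$rx_duration_days[1L],
      first_line_first_obs = as.numeric(cov$line[1L] == "first"),
      fdc_first_obs = as.numeric(cov$fdc[1L]),
      stringsAsFactors = FALSE)
  }

  members <- if (length(members)) do.call(rbind, members) else NULL
  tally <- exclusion_tally(nrow(patients), counts[["under_age"]],
                           counts[["no_rx_in_observation"]],
                           counts[["not_enrolled_before"]],
                           counts[["delayed_phone_capture"]],
                           counts[["no_observation_time"]])
  stopifnot(tally$included == NROW(members))
  structure(list(members = members, coverage = coverage, tally = tally,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else
                   data.frame(patient_id = character(0), reason = character(0)),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d members (of %d screened)\n",
              nrow(x$members), x$tally$total_screened))
  print(table(x$members$group))
  invisible(x)
}

#' Mean substitution for missing covariates
#'
#' Replaces each missing non-prescription covariate (age, female indicator)
#' with the mean of the available values among included cohort members; the
#' `missing_any` indicator marks members with at least one substituted
#' value. Mean substitution leaves each covariate's cohort mean unchanged.
#'
#' @param cohort A [build_cohort()] result.
#' @return The cohort with completed covariates.
#' @export
impute_missing <- function(cohort) {
  m <- cohort$members
  for (col in c("age_years", "female")) {
    miss <- is.na(m[[col]])
    if (all(miss)) stop("impute_missing: '", col, "' missing for all members")
    if (any(miss)) m[[col]][miss] <- mean(m[[col]][!miss])
  }
  cohort$members <- m
  cohort
}

#' Restrict a cohort to an analysis subset
#'
#' `below_100_baseline` keeps members whose pre-program coverage is defined
#' and below 100% (at least one apparently missed prescription at
#' baseline). `recent_initiators` keeps members who started ART within two
#' years (730.5 days, inclusive) of the program launch. `full` is the
#' identity.
#'
#' @param cohort A [build_cohort()] result.
#' @param which One of `"full"`, `"below_100_baseline"`,
#'   `"recent_initiators"`.
#' @return The restricted cohort (same class).
#' @export
select_subset <- function(cohort,
                          which = c("full", "below_100_baseline",
                                    "recent_initiators")) {
  which <- match.arg(which)
  m <- cohort$members
  keep <- switch(which,
    full = rep(TRUE, nrow(m)),
    below_100_baseline = !is.na(m$pre_program_coverage) &
      m$pre_program_coverage < 1,
    recent_initiators =
      as.numeric(cohort$config$program_start - m$art_start_date) <= 730.5)
  cohort$members <- m[keep, , drop = FALSE]
  cohort$coverage <- cohort$coverage[cohort$members$patient_id]
  cohort$subset <- which
  cohort
}

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[2L], q[1L], q[3L])
}

n_pct <- function(flag) {
  sprintf("%d (%.1f%%)", sum(flag, na.rm = TRUE), 100 * mean(flag, na.rm = TRUE))
}

anova_p <- function(y, g) {
  if (length(unique(g)) < 2L || all(is.na(y))) return(NA_real_)
  if (stats::var(y, na.rm = TRUE) == 0) return(1)
  stats::anova(stats::aov(y ~ g))[["Pr(>F)"]][1L]
}

chisq_p <- function(flag, g) {
  tab <- table(g, flag)
  if (any(dim(tab) < 2L)) return(1)
  suppressWarnings(stats::chisq.test(tab)$p.value)
}

#' Baseline characteristics table
#'
#' Summarizes the cohort by exposure group: continuous variables as median
#' (IQR) with one-way ANOVA p-values, categorical variables as n (%) with
#' chi-squared p-values; both an all-groups comparison and an
#' Exposed-vs-Unexposed comparison are reported. Prescription-derived rows
#' use the prescription active at each member's first observed day; age and
#' ART duration are taken at the start of data availability.
#'
#' @param cohort A [build_cohort()] (optionally subset) result.
#' @return A data frame of class `baseline_table` with columns `variable`,
#'   one formatted column per group, `p_all`, `p_exposed_vs_unexposed`.
#' @export
baseline_table <- function(cohort) {
  m <- cohort$members
  cfg <- cohort$config
  m$art_years <- as.numeric(cfg$data_start - m$art_start_date) / 365.25
  m$rx_cat <- cut(m$rx_len_first_obs, breaks = c(0, 31, 62, 93, Inf),
                  labels = c("1-month", "2-month", "3-month", "6-month"))
  m$no_pre <- is.na(m$pre_program_coverage)
  m$transfer <- !is.na(m$transfer_out_date) &
    m$transfer_out_date <= m$window_end & m$transfer_out_date >= m$window_start

  groups <- c("Exposed", "Unexposed", "Unknown")
  sub2 <- m[m$group %in% c("Exposed", "Unexposed"), ]
  by_grp <- function(f, col) {
    vapply(groups, function(g) f(m[[col]][m$group == g]), character(1))
  }

  rows <- list()
  add <- function(variable, cells, p_all, p2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, Exposed = cells[1L], Unexposed = cells[2L],
      Unknown = cells[3L], p_all = p_all, p_exposed_vs_unexposed = p2,
      stringsAsFactors = FALSE)
  }

  cont <- c("Age in years (IQR)" = "age_years",
            "ART duration in years (IQR)" = "art_years",
            "Prescription length in days (IQR)" = "rx_len_first_obs")
  for (v in names(cont)) {
    col <- cont[[v]]
    add(v, by_grp(median_iqr, col),
        anova_p(m[[col]], m$group), anova_p(sub2[[col]], sub2$group))
  }
  cats <- c("Female" = "female",
            "First line regimen" = "first_line_first_obs",
            "Fixed dose combination" = "fdc_first_obs",
            "No pre-program observation time" = "no_pre",
            "Transfer out during observation" = "transfer",
            "Any missing covariate" = "missing_any")
  for (v in names(cats)) {
    col <- cats[[v]]
    flag <- m[[col]] > 0
    add(v, vapply(groups, function(g) n_pct(flag[m$group == g]), character(1)),
        chisq_p(flag, m$group), chisq_p(flag[m$group %in% c("Exposed", "Unexposed")],
                                        sub2$group))
  }
  # prescription-length mix: one multi-level chi-squared test, one row per level
  p_mix_all <- suppressWarnings(stats::chisq.test(table(m$group, m$rx_cat))$p.value)
  p_mix_2 <- suppressWarnings(stats::chisq.test(table(sub2$group, sub2$rx_cat))$p.value)
  for (lev in levels(m$rx_cat)) {
    flag <- m$rx_cat == lev
    add(sprintf("%s prescriptions", lev),
        vapply(groups, function(g) n_pct(flag[m$group == g]), character(1)),
        p_mix_all, p_mix_2)
    p_mix_all <- NA_real_; p_mix_2 <- NA_real_  # report the joint test once
  }

  out <- do.call(rbind, rows)
  attr(out, "group_n") <- table(factor(m$group, levels = groups))
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' @export
print.baseline_table <- function(x, ...) {
  n <- attr(x, "group_n")
  cat(sprintf("Baseline characteristics (Exposed n=%d, Unexposed n=%d, Unknown n=%d)\n\n",
              n[["Exposed"]], n[["Unexposed"]], n[["Unknown"]]))
  df <- as.data.frame(x)
  df$p_all <- ifelse(is.na(df$p_all), "", formatC(df$p_all, digits = 3, format = "f"))
  df$p_exposed_vs_unexposed <- ifelse(is.na(df$p_exposed_vs_unexposed), "",
                                      formatC(df$p_exposed_vs_unexposed,
                                              digits = 3, format = "f"))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Paired comparison of >95% coverage before versus during the program
#'
#' Among members observed in both periods, pairs the indicator
#' "coverage above 95%" across periods and applies the exact binomial
#' McNemar test (two-sided) to the discordant pairs.
#'
#' @param cohort A [build_cohort()] result (optionally restricted to one
#'   exposure group beforehand).
#' @return An object of class `htest` with the discordant-pair counts
#'   (`b`: above 95% pre-program only; `c`: above 95% during program only)
#'   and the exact two-sided p-value.
#' @export
mcnemar_gt95 <- function(cohort) {
  m <- cohort$members
  b <- 0L; c_ <- 0L; n_pairs <- 0L
  for (pid in m$patient_id) {
    cov <- cohort$coverage[[pid]]
    pre <- cov$period == "pre_program"
    if (!any(pre) || all(pre)) next
    n_pairs <- n_pairs + 1L
    hi_pre <- mean(cov$covered[pre]) > 0.95
    hi_dur <- mean(cov$covered[!pre]) > 0.95
    if (hi_pre && !hi_dur) b <- b + 1L
    if (!hi_pre && hi_dur) c_ <- c_ + 1L
  }
  nd <- b + c_
  p <- if (nd == 0L) 1 else min(1, 2 * stats::pbinom(min(b, c_), nd, 0.5))
  structure(list(statistic = c(discordant = nd),
                 estimate = c(b = b, c = c_),
                 p.value = p,
                 method = "Exact binomial McNemar test on >95% coverage, pre vs during program",
                 data.name = sprintf("%d paired members", n_pairs)),
            class = "htest")
}
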
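# Synthetic clinic-data generator. Two modes:
#  - behavioral: prescription histories from a refill process with delayed
#    (and occasionally early) refills, exercising the full pipeline from CSV
#    parsing through the coverage engine;
#  - model_faithful: patient-day outcome rows drawn directly from the
#    random-intercept logistic data-generating equation, for exact
#    parameter-recovery studies.

FIRST_LINE_AGENTS <- "EFV;FTC;TDF"
SECOND_LINE_AGENTS <- "3TC;AZT;LPV"

#' Simulation configuration
#'
#' Defaults emulate the composition of the evaluated clinic cohort: group
#' mix 78.5/14.0/7.5% (Exposed/Unexposed/Unknown), 70% female, median age
#' 37.7 (IQR 32.4-43.9) years, a prescription-length mix dominated by
#' 6-month scripts, ~3.4% transfer-out, duplicate re-recordings of 6-month
#' prescriptions, and sparse missing covariates.
#'
#' @param n_patients Number of patients (default 300; use 2255 for a
#'   cohort-sized clinic).
#' @param seed Integer seed; all randomness derives from it via per-patient
#'   substreams, so adding a patient never perturbs the others.
#' @param group_probs Named simplex over Exposed/Unexposed/Unknown.
#' @param p_female Probability of female gender.
#' @param age_median,age_iqr Target median and IQR of age in years; ages
#'   are drawn from the log-normal matching them.
#' @param rx_length_mix Named distribution over prescription lengths 30,
#'   60, 90, 180 days.
#' @param p_first_line Probability a patient is on a first-line regimen.
#' @param p_fdc_initial,p_fdc_late Fixed-dose-combination probability for
#'   prescriptions issued before the program start, ramping linearly to
#'   `p_fdc_late` at the end of data (the formulation rollout).
#' @param p_transfer_out Probability of transfer-out during observation.
#' @param p_duplicate_rerecord Probability a 180-day prescription spawns a
#'   re-recorded 90-day balance record.
#' @param p_missing_covariate Probability each of birth date and gender is
#'   missing from the chart.
#' @param true_effect_or Target program-effect (Exposed x during-program)
#'   odds ratio on daily coverage.
#' @param sigma_u Patient random-intercept SD. In model-faithful mode this
#'   is the SD on the daily-coverage logit scale; in behavioral mode the
#'   intercept enters the refill model, and the SD later estimated on the
#'   daily-coverage scale is larger, because missed refills produce runs
#'   of correlated uncovered days that the daily model attributes to the
#'   patient effect.
#' @param baseline_logit Model-faithful intercept: logit of daily coverage
#'   for a pre-program Unexposed male patient of age 38.
#' @param mode `"behavioral"` or `"model_faithful"`.
#' @param refill_logit Behavioral mode: log-odds that a refill is on time
#'   for a patient with random intercept 0, before any program effect.
#' @param mean_gap_days Behavioral mode: mean of the geometric refill-gap
#'   length when a refill is late.
#' @param p_early,mean_early_days Behavioral mode: probability that a
#'   refill arrives early (creating carryover), and the mean early margin.
#' @param gap_effect Behavioral mode: additive log-odds boost to on-time
#'   refills for Exposed patients during the program. The default was
#'   frozen from a [calibrate_gap_effect()] run at these settings so the
#'   realized daily-coverage odds ratio approximates `true_effect_or`.
#' @param unknown_gap_effect Behavioral mode: analogous shift for the
#'   Unknown group during the program (negative: missing-chart patients
#'   tend to have adherence challenges).
#' @param p_line_switch Per-refill probability of switching to second-line
#'   agents (forfeits carryover).
#' @param p_delayed_capture Probability an Exposed patient's phone number
#'   was captured only after the observation period began.
#' @param p_opt_out Probability an Exposed patient later opts out (inert
#'   for the intention-to-treat estimand; recorded as an event).
#' @param or_period,or_exposed_pre,or_unknown_pre,or_unknown_program,
#'   or_age_per_year,or_female Model-faithful mode: the remaining true
#'   odds ratios of the data-generating equation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 300L, seed = 1L,
                       group_probs = c(Exposed = 0.785, Unexposed = 0.140,
                                       Unknown = 0.075),
                       p_female = 0.70,
                       age_median = 37.7, age_iqr = c(32.4, 43.9),
                       rx_length_mix = c("30" = 0.13, "60" = 0.155,
                                         "90" = 0.125, "180" = 0.59),
                       p_first_line = 0.946,
                       p_fdc_initial = 0.016, p_fdc_late = 0.25,
                       p_transfer_out = 0.034,
                       p_duplicate_rerecord = 0.5,
                       p_missing_covariate = 0.02,
                       true_effect_or = 1.25,
                       sigma_u = 0.8,
                       baseline_logit = 2.75,
                       mode = c("behavioral", "model_faithful"),
                       refill_logit = 0,
                       mean_gap_days = 12,
                       p_early = 0.25, mean_early_days = 7,
                       gap_effect = NULL,
                       unknown_gap_effect = -0.8,
                       p_line_switch = 0.02,
                       p_delayed_capture = 0.001,
                       p_opt_out = 0.10,
                       or_period = 0.8,
                       or_exposed_pre = 1.05,
                       or_unknown_pre = 1.6,
                       or_unknown_program = 0.47,
                       or_age_per_year = 1.02,
                       or_female = 1.2) {
  mode <- match.arg(mode)
  if (abs(sum(group_probs) - 1) > 1e-8 || any(group_probs < 0)) {
    stop("sim_config: group_probs must be a simplex over the three groups")
  }
  probs <- c(p_female, p_fdc_initial, p_fdc_late, p_transfer_out,
             p_duplicate_rerecord, p_missing_covariate, p_early,
             p_line_switch, p_delayed_capture, p_opt_out)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must lie in [0, 1]")
  if (abs(sum(rx_length_mix) - 1) > 1e-8) {
    stop("sim_config: rx_length_mix must sum to 1")
  }
  if (true_effect_or <= 0) stop("sim_config: true_effect_or must be positive")
  if (is.null(gap_effect)) gap_effect <- GAP_EFFECT_DEFAULT
  cfg <- mget(names(formals()), envir = environment())
  class(cfg) <- "sim_config"
  cfg
}

# Frozen from one calibrate_gap_effect() run at sim_config() defaults
# (calibration n = 6000 patients): realized conditional coverage OR 1.26,
# within 2% of the 1.25 target.
GAP_EFFECT_DEFAULT <- 0.5625

# log-normal parameters matching a target median and IQR
age_lnorm_params <- function(med, iqr) {
  list(meanlog = log(med),
       sdlog = log(iqr[2L] / iqr[1L]) / (2 * stats::qnorm(0.75)))
}

patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 100003) %% 2147483647)
}

ramped_p_fdc <- function(issue, cfg, study) {
  if (issue < study$program_start) return(cfg$p_fdc_initial)
  frac <- as.numeric(issue - study$program_start) /
    as.numeric(study$data_end - study$program_start)
  cfg$p_fdc_initial + (cfg$p_fdc_late - cfg$p_fdc_initial) * frac
}

simulate_patient <- function(i, cfg, study, aln) {
  set.seed(patient_seed(cfg$seed, i))
  pid <- sprintf("P%05d", i)
  grp <- sample(names(cfg$group_probs), 1L, prob = cfg$group_probs)
  female <- stats::runif(1) < cfg$p_female
  age <- min(max(stats::rlnorm(1, aln$meanlog, aln$sdlog), 18.5), 85)
  birth_date <- study$data_start - round(age * 365.25)
  years_before <- max(stats::rnorm(1, 3.3, 1.5), 0.1)
  enrollment <- study$program_start - round(years_before * 365.25)
  art_start <- enrollment + sample(0:30, 1L)
  transfer <- if (stats::runif(1) < cfg$p_transfer_out) {
    max(study$obs_start +
          sample.int(as.integer(study$data_end - study$obs_start), 1L),
        enrollment + 30L)  # transfer-out never precedes enrollment
  } else as.Date(NA)

  capture <- as.Date(NA)
  status <- switch(grp, Exposed = "available", Unexposed = "absent",
                   Unknown = "unknown")
  if (grp == "Exposed") {
    capture_pool <- c(seq(as.Date("2012-06-01"), as.Date("2012-07-31"), "day"),
                      seq(as.Date("2013-06-01"), as.Date("2013-06-30"), "day"))
    capture <- sample(capture_pool, 1L)
    if (stats::runif(1) < cfg$p_delayed_capture) {
      capture <- study$obs_start + sample(0:30, 1L)
    }
  }

  u <- stats::rnorm(1, 0, cfg$sigma_u)
  lens <- as.integer(names(cfg$rx_length_mix))
  primary_len <- sample(lens, 1L, prob = cfg$rx_length_mix)
  line <- if (stats::runif(1) < cfg$p_first_line) "first" else "second"
  agents <- if (line == "first") FIRST_LINE_AGENTS else SECOND_LINE_AGENTS

  issue <- max(study$data_start, art_start) + sample(0:45, 1L)
  rx <- list()
  while (issue <= study$data_end) {
    dur <- if (stats::runif(1) < 0.8) primary_len else
      sample(lens, 1L, prob = cfg$rx_length_mix)
    if (line == "first" && stats::runif(1) < cfg$p_line_switch) {
      line <- "second"; agents <- SECOND_LINE_AGENTS
    }
    fdc <- stats::runif(1) < ramped_p_fdc(issue, cfg, study)
    rx[[length(rx) + 1L]] <- data.frame(
      patient_id = pid, issue_date = issue, duration_days = dur,
      agents = agents, line = line, fdc = fdc, stringsAsFactors = FALSE)
    if (dur == 180L && stats::runif(1) < cfg$p_duplicate_rerecord) {
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = pid, issue_date = issue + 90L, duration_days = 90L,
        agents = agents, line = line, fdc = fdc, stringsAsFactors = FALSE)
    }
    scheduled <- issue + dur  # day after the last covered day
    during <- scheduled >= study$program_start
    eff <- cfg$gap_effect * (grp == "Exposed" && during) +
      cfg$unknown_gap_effect * (grp == "Unknown" && during)
    if (stats::runif(1) < cfg$p_early) {
      early <- min(stats::rgeom(1, 1 / cfg$mean_early_days) + 1L, dur - 1L)
      issue <- scheduled - early
    } else {
      on_time <- stats::runif(1) < stats::plogis(cfg$refill_logit + u + eff)
      gap <- if (on_time) 0L else stats::rgeom(1, 1 / cfg$mean_gap_days) + 1L
      issue <- scheduled + gap
    }
  }

  miss_birth <- stats::runif(1) < cfg$p_missing_covariate
  miss_gender <- stats::runif(1) < cfg$p_missing_covariate

  events <- list()
  opt_out <- as.Date(NA)
  if (grp == "Exposed") {
    events[[1L]] <- data.frame(patient_id = pid, event = "intro_sent",
                               event_date = study$program_start,
                               stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.727) {
      events[[length(events) + 1L]] <- data.frame(
        patient_id = pid, event = "delivery_confirmed",
        event_date = as.Date("2014-01-13") +
          sample(0:as.integer(study$data_end - as.Date("2014-01-13")), 1L),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < cfg$p_opt_out) {
      opt_out <- study$program_start +
        sample.int(as.integer(study$data_end - study$program_start), 1L)
      events[[length(events) + 1L]] <- data.frame(
        patient_id = pid, event = "opt_out", event_date = opt_out,
        stringsAsFactors = FALSE)
    }
  }

  patient <- data.frame(
    patient_id = pid, enrollment_date = enrollment,
    birth_date = if (miss_birth) as.Date(NA) else birth_date,
    gender = if (miss_gender) NA_character_ else
      if (female) "female" else "male",
    art_start_date = art_start, transfer_out_date = transfer,
    phone_status = status, phone_capture_date = capture,
    opt_out_date = opt_out, stringsAsFactors = FALSE)

  list(patient = patient,
       prescriptions = do.call(rbind, rx),
       events = if (length(events)) do.call(rbind, events) else NULL,
       u = u, group = grp, age = age, female = as.numeric(female))
}

simulate_model_faithful <- function(cfg, study) {
  aln <- age_lnorm_params(cfg$age_median, cfg$age_iqr)
  n_pre <- as.integer(study$program_start - study$obs_start)
  n_dur <- as.integer(study$data_end - study$program_start) + 1L
  lens <- as.integer(names(cfg$rx_length_mix))
  pieces <- vector("list", cfg$n_patients)
  u_all <- numeric(cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i))
    pid <- sprintf("P%05d", i)
    grp <- sample(names(cfg$group_probs), 1L, prob = cfg$group_probs)
    female <- as.numeric(stats::runif(1) < cfg$p_female)
    age <- min(max(stats::rlnorm(1, aln$meanlog, aln$sdlog), 18.5), 85)
    u <- stats::rnorm(1, 0, cfg$sigma_u)
    u_all[i] <- u
    rx_len <- sample(lens, 1L, prob = cfg$rx_length_mix)
    first_line <- as.numeric(stats::runif(1) < cfg$p_first_line)
    fdc <- as.numeric(stats::runif(1) < cfg$p_fdc_initial)
    art_months <- stats::runif(1, 6, 60) / 12 * 365.25 / 30

    base <- cfg$baseline_logit + log(cfg$or_age_per_year) * (age - 38) +
      log(cfg$or_female) * female +
      log(cfg$or_exposed_pre) * (grp == "Exposed") +
      log(cfg$or_unknown_pre) * (grp == "Unknown") + u
    lp_dur <- base + log(cfg$or_period) +
      log(cfg$true_effect_or) * (grp == "Exposed") +
      log(cfg$or_unknown_program) * (grp == "Unknown")
    covered <- c(stats::rbinom(n_pre, 1L, stats::plogis(base)),
                 stats::rbinom(n_dur, 1L, stats::plogis(lp_dur)))
    pieces[[i]] <- data.frame(
      patient_id = pid, covered = covered,
      period = rep(c("pre_program", "during_program"), c(n_pre, n_dur)),
      group = grp, age_years = age, female = female,
      art_duration_30d = art_months, rx_length_30d = rx_len / 30,
      first_line = first_line, fdc = fdc, missing_any = 0,
      stringsAsFactors = FALSE)
  }
  truth <- unclass(cfg)[c("true_effect_or", "sigma_u", "baseline_logit", "or_period",
                 "or_exposed_pre", "or_unknown_pre", "or_unknown_program",
                 "or_age_per_year", "or_female")]
  truth$u <- u_all
  list(rows = do.call(rbind, pieces), truth = truth)
}

#' Generate a synthetic clinic
#'
#' In behavioral mode, returns the three standard tables (patients,
#' prescriptions, program events) produced by a refill process: at each
#' prescription's scheduled end the next issue is on time with a
#' probability from a logistic model with a patient intercept and a
#' group-by-period effect, delayed by a geometric gap otherwise, and
#' occasionally early (exercising the carryover rule); 180-day
#' prescriptions spawn duplicate balance re-recordings. In model-faithful
#' mode, returns a ready-made patient-day outcome table drawn exactly from
#' the random-intercept logistic data-generating equation. Either way the
#' output is deterministic given `config$seed`, and `truth` records every
#' latent parameter for recovery studies.
#'
#' @param config A [sim_config()].
#' @param study A [study_config()].
#' @return Behavioral mode: a list with `patients`, `prescriptions`,
#'   `events`, `truth`. Model-faithful mode: a list with `rows` (patient-
#'   day table) and `truth`.
#' @export
simulate_clinic <- function(config = sim_config(), study = study_config()) {
  if (config$mode == "model_faithful") {
    return(simulate_model_faithful(config, study))
  }
  aln <- age_lnorm_params(config$age_median, config$age_iqr)
  out <- lapply(seq_len(config$n_patients), simulate_patient,
                cfg = config, study = study, aln = aln)
  patients <- do.call(rbind, lapply(out, `[[`, "patient"))
  prescriptions <- do.call(rbind, lapply(out, `[[`, "prescriptions"))
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$issue_date), ]
  rownames(prescriptions) <- NULL
  ev <- Filter(Negate(is.null), lapply(out, `[[`, "events"))
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(patient_id = character(0), event = character(0),
               event_date = as.Date(character(0)))
  rownames(events) <- NULL
  truth <- unclass(config)[c("true_effect_or", "sigma_u", "gap_effect",
                    "unknown_gap_effect", "refill_logit", "mean_gap_days",
                    "p_early", "mean_early_days")]
  truth$u <- vapply(out, `[[`, numeric(1), "u")
  list(patients = patients, prescriptions = prescriptions, events = events,
       truth = truth)
}

#' Write a simulated clinic to CSV
#'
#' Emits the three standard tables plus `truth.yaml` into a directory.
#'
#' @param sim A behavioral-mode [simulate_clinic()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_clinic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients(sim$patients, file.path(dir, "patients.csv"))
  write_prescriptions(sim$prescriptions, file.path(dir, "prescriptions.csv"))
  write_events(sim$events, file.path(dir, "events.csv"))
  truth <- sim$truth
  truth$u <- NULL  # per-patient intercepts stay in memory only
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Calibrate the behavioral refill effect to a target coverage odds ratio
#'
#' Bisection on the on-time-refill log-odds boost (`gap_effect`) until the
#' realized conditional daily-coverage odds ratio — estimated by pushing a
#' large behavioral simulation through the cohort builder and fitting the
#' unadjusted group-by-period random-intercept model — matches
#' `config$true_effect_or` within `tol`.
#'
#' @param config A behavioral [sim_config()].
#' @param study A [study_config()].
#' @param n_cal Number of calibration patients per evaluation.
#' @param tol Relative tolerance on the realized odds ratio.
#' @param lower,upper Bisection bracket on the log-odds effect.
#' @param max_iter Maximum bisection steps.
#' @return A list with the calibrated `gap_effect` and the trace of
#'   evaluated points.
#' @export
calibrate_gap_effect <- function(config = sim_config(), study = study_config(),
                                 n_cal = 2000L, tol = 0.02,
                                 lower = 0, upper = 3, max_iter = 12L) {
  target <- config$true_effect_or
  realized <- function(effect) {
    cfg <- config
    cfg$gap_effect <- effect
    cfg$n_patients <- as.integer(n_cal)
    sim <- simulate_clinic(cfg, study)
    cohort <- impute_missing(build_cohort(sim$patients, sim$prescriptions, study))
    rows <- build_daily_dataset(cohort)
    fit <- fit_coverage_model(rows, covariates = character(0))
    fit$contrasts$OR_program_Exposed[["or"]]
  }
  trace <- data.frame(effect = numeric(0), or = numeric(0))
  lo <- lower; hi <- upper
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    or <- realized(mid)
    trace <- rbind(trace, data.frame(effect = mid, or = or))
    if (abs(or / target - 1) <= tol) break
    if (or < target) lo <- mid else hi <- mid
  }
  list(gap_effect = mid, realized_or = or, trace = trace)
}

#' Summarize parameter recovery across simulation replicates
#'
#' @param true_or The true program-effect odds ratio used to generate the
#'   replicates.
#' @param fits A list of `coverage_fit` objects, one per replicate.
#' @return A list with `n`, `mean_or`, `bias`, `rmse` (on the log-OR
#'   scale), `ci_coverage`, and the per-replicate estimates.
#' @export
summarize_recovery <- function(true_or, fits) {
  est <- t(vapply(fits, function(f) f$contrasts$OR_program_Exposed,
                  numeric(4)))
  covered <- est[, "ci_low"] <= true_or & true_or <= est[, "ci_high"]
  list(n = length(fits),
       mean_or = mean(est[, "or"]),
       bias = mean(log(est[, "or"])) - log(true_or),
       rmse = sqrt(mean((log(est[, "or"]) - log(true_or))^2)),
       ci_coverage = mean(covered),
       estimates = est)
}
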
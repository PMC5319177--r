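cfg <- study_config()

test_that("patient-day dataset conserves rows and carries time-varying fields", {
  pats <- rbind(mk_patient("A", art_start = "2012-01-15"),
                mk_patient("B", status = "absent", capture = NA))
  rx <- rbind(mk_rx("A", "2013-05-01", 90),            # window opens 2013-07-30
              mk_rx("A", "2013-09-20", 180),
              mk_rx("B", "2013-01-01", 180),
              mk_rx("B", "2013-07-10", 180))           # window opens at obs start
  co <- impute_missing(build_cohort(pats, rx, cfg))
  rows <- build_daily_dataset(co)
  expect_equal(nrow(rows),
               sum(as.numeric(co$members$window_end - co$members$window_start) + 1))
  # boundary labeling: the day before program start is pre-program
  b_rows <- rows[rows$patient_id == "B", ]
  dates_b <- seq(co$members$window_start[co$members$patient_id == "B"],
                 co$members$window_end[co$members$patient_id == "B"], "day")
  expect_identical(b_rows$period[dates_b == as.Date("2013-09-08")], "pre_program")
  expect_identical(b_rows$period[dates_b == as.Date("2013-09-09")], "during_program")

  # 600 days on ART -> 20.0 in 30-day units
  a_rows <- rows[rows$patient_id == "A", ]
  dates_a <- seq(co$members$window_start[co$members$patient_id == "A"],
                 co$members$window_end[co$members$patient_id == "A"], "day")
  on_600 <- dates_a == as.Date("2012-01-15") + 600
  expect_equal(a_rows$art_duration_30d[on_600], 20.0)
  # active prescription length carried forward across the uncovered gap
  in_gap <- dates_a == as.Date("2013-08-15")  # after 90-day rx ended
  expect_equal(a_rows$rx_length_30d[in_gap], 3)
  expect_equal(a_rows$covered[in_gap], 0L)
})

test_that("odds-division translation matches closed-form arithmetic", {
  # printed inputs: 94.1% coverage, AOR 1.23 -> about 4.6 days/year
  expect_equal(coverage_days_gained(0.941, 1.23, 365.25), 4.602, tolerance = 1e-3)
  expect_identical(coverage_days_gained(0.75, 1, 365.25), 0)
  expect_equal(coverage_days_gained(0.5, 2, 365.25), (0.5 - 1 / 3) * 365.25)
  expect_error(coverage_days_gained(1, 1.2), "strictly inside")
  expect_error(coverage_days_gained(0.9, -1), "or_effect")

  # strictly increasing in the odds ratio
  ors <- seq(0.5, 3, by = 0.25)
  vals <- coverage_days_gained(0.9, ors)
  expect_true(all(diff(vals) > 0))

  # round-trip: recovering the OR from the two probabilities
  p_avg <- 0.941
  days <- coverage_days_gained(p_avg, 1.23, 1)
  p_hypo <- p_avg - days
  or_back <- (p_avg / (1 - p_avg)) / (p_hypo / (1 - p_hypo))
  expect_equal(or_back, 1.23, tolerance = 1e-10)
})

test_that("with no patient heterogeneity the mixed model matches plain logistic regression", {
  sim <- simulate_clinic(sim_config(n_patients = 400, seed = 4, sigma_u = 0,
                                    mode = "model_faithful"))
  fit <- fit_coverage_model(sim$rows, covariates = c("age_years", "female"),
                            nAGQ = 1L)
  expect_lt(fit$sigma_u, 0.1)
  glm_fit <- stats::glm(covered ~ group * period + age_years + female,
                        data = transform(sim$rows,
                                         group = factor(group, c("Unexposed", "Exposed", "Unknown")),
                                         period = factor(period, c("pre_program", "during_program"))),
                        family = stats::binomial())
  mixed <- coef(fit)
  plain <- coef(glm_fit)
  shared <- intersect(names(mixed), names(plain))
  expect_gt(length(shared), 5L)
  expect_equal(mixed[shared], plain[shared], tolerance = 0.02)
})

test_that("backward elimination retains a priori terms and prunes noise", {
  sim <- simulate_clinic(sim_config(n_patients = 200, seed = 9,
                                    mode = "model_faithful"))
  rows <- sim$rows
  set.seed(31)
  # a pure-noise patient-level covariate
  noise <- setNames(rnorm(length(unique(rows$patient_id))),
                    unique(rows$patient_id))
  rows$noise_cov <- noise[rows$patient_id]
  el <- backward_eliminate(rows, covariates = c("age_years", "noise_cov"),
                           p_threshold = 0.25, nAGQ = 1L)
  # group, period and interaction always present in the final fit
  terms <- el$fit$coefficients$term
  expect_true(all(c("groupExposed", "periodduring_program",
                    "groupExposed:periodduring_program") %in% terms))
  # every removal logged with its p-value above the threshold
  if (nrow(el$log)) expect_true(all(el$log$p > 0.25))
  # retained candidates all sit at or below the threshold
  kept_p <- el$fit$coefficients$p[match(el$covariates, terms)]
  if (length(kept_p)) expect_true(all(kept_p <= 0.25))
})

test_that("a pure-noise covariate is eliminated at roughly the null rate", {
  removed <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    sim <- simulate_clinic(sim_config(n_patients = 120, seed = 100 + r,
                                      mode = "model_faithful"))
    rows <- sim$rows
    set.seed(300 + r)
    noise <- setNames(rnorm(length(unique(rows$patient_id))),
                      unique(rows$patient_id))
    rows$noise_cov <- noise[rows$patient_id]
    el <- backward_eliminate(rows, covariates = "noise_cov", nAGQ = 1L)
    if ("noise_cov" %in% el$log$removed) removed <- removed + 1L
  }
  # under the null the removal probability is 0.75; allow wide Monte Carlo
  # slack at 15 replicates (P(6 <= X <= 15) > 0.999 for Binom(15, 0.75))
  expect_gte(removed, 6L)
})

test_that("run_analysis rejects subsets with fewer than two exposure groups", {
  pats <- rbind(mk_patient("A"), mk_patient("B", capture = "2013-05-01"))
  rx <- rbind(mk_rx("A", "2013-07-01", 180), mk_rx("B", "2013-07-01", 180))
  co <- impute_missing(build_cohort(pats, rx, cfg))
  expect_error(run_analysis(co, "full"), "fewer than 2 exposure groups")
})

test_that("an effect concentrated in low-baseline patients is larger in that subset", {
  # fabricate a cohort whose daily outcomes follow the logistic model, with
  # the program effect confined to patients with imperfect baseline coverage
  set.seed(77)
  n <- 240L
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("Exposed", "Unexposed"), length.out = n)
  low_baseline <- rep(c(TRUE, FALSE), each = n / 2)
  members <- list(); coverage <- list()
  pre_dates <- seq(cfg$obs_start, cfg$program_start - 1, "day")
  dur_dates <- seq(cfg$program_start, cfg$data_end, "day")
  for (i in seq_len(n)) {
    u <- rnorm(1, 0, 0.5)
    base <- 2.2 + u
    # low-baseline patients are imperfect pre-program and receive the
    # effect when Exposed; perfect-baseline patients have noisy
    # during-program outcomes but no program effect, so they dilute the
    # full-cohort interaction toward 1
    eff <- if (low_baseline[i] && grp[i] == "Exposed") log(2.5) else 0
    cov_pre <- if (low_baseline[i]) {
      x <- rbinom(length(pre_dates), 1, plogis(base)) == 1
      x[1] <- FALSE  # force imperfection: subset membership deterministic
      x
    } else rep(TRUE, length(pre_dates))
    cov_dur <- rbinom(length(dur_dates), 1, plogis(base + eff)) == 1
    series <- data.frame(
      date = c(pre_dates, dur_dates),
      covered = c(cov_pre, cov_dur),
      period = rep(c("pre_program", "during_program"),
                   c(length(pre_dates), length(dur_dates))),
      rx_duration_days = 90, line = "first", fdc = FALSE,
      stringsAsFactors = FALSE)
    coverage[[ids[i]]] <- series
    members[[i]] <- data.frame(
      patient_id = ids[i], group = grp[i],
      window_start = pre_dates[1], window_end = dur_dates[length(dur_dates)],
      has_pre_program_time = TRUE, age_years = 38, female = 1,
      art_start_date = as.Date("2011-01-01"), transfer_out_date = as.Date(NA),
      pre_program_coverage = mean(cov_pre), missing_any = 0,
      rx_len_first_obs = 90, first_line_first_obs = 1, fdc_first_obs = 0,
      stringsAsFactors = FALSE)
  }
  co <- structure(list(members = do.call(rbind, members), coverage = coverage,
                       config = cfg), class = "cohort")
  an_full <- run_analysis(co, "full", covariates = character(0))
  an_low <- run_analysis(co, "below_100_baseline", covariates = character(0))
  expect_gt(an_low$fit$contrasts$OR_program_Exposed[["or"]],
            an_full$fit$contrasts$OR_program_Exposed[["or"]])
  expect_gt(an_low$days_gained_per_year, 0)
})
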
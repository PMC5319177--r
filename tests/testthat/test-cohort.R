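cfg <- study_config()

test_that("inclusion criteria apply in order, each patient counted once", {
  pats <- rbind(
    mk_patient("A"),                                   # eligible
    mk_patient("B", birth = "1995-06-01"),             # 17.4y at data start
    mk_patient("C", enrollment = "2013-08-01"),        # enrolled too late
    mk_patient("D", status = "absent", capture = NA),  # eligible, Unexposed
    mk_patient("E", status = "unknown", capture = NA)) # eligible, Unknown
  rx <- do.call(rbind, lapply(pats$patient_id, function(id)
    mk_rx(id, "2013-07-10", 90)))
  co <- build_cohort(pats, rx, cfg)
  tl <- co$tally
  expect_equal(unlist(tl, use.names = FALSE), c(5L, 1L, 0L, 1L, 0L, 0L, 3L))
  expect_setequal(co$members$patient_id, c("A", "D", "E"))
  expect_equal(tl$included + sum(unlist(tl[rxcover:::EXCLUSION_REASONS])),
               tl$total_screened)
})

test_that("group assignment is intention-to-treat and order-invariant", {
  pats <- rbind(
    mk_patient("OPT", capture = "2013-06-15", opt_out = "2013-10-01"),
    mk_patient("ABS", status = "absent", capture = NA),
    mk_patient("UNK", status = "unknown", capture = NA))
  rx <- do.call(rbind, lapply(pats$patient_id, function(id)
    mk_rx(id, "2013-07-10", 90)))
  co <- build_cohort(pats, rx, cfg)
  grp <- setNames(co$members$group, co$members$patient_id)
  # opt-out is disregarded: the patient was sent messages
  expect_equal(grp[["OPT"]], "Exposed")
  expect_equal(grp[["ABS"]], "Unexposed")
  expect_equal(grp[["UNK"]], "Unknown")

  co2 <- build_cohort(pats[c(3, 1, 2), ], rx, cfg)
  grp2 <- setNames(co2$members$group, co2$members$patient_id)
  expect_equal(grp2[names(grp)], grp)
})

test_that("mean substitution completes covariates and preserves means", {
  pats <- rbind(
    mk_patient("A", birth = "1982-11-04"),   # age 30.0
    mk_patient("B", birth = "1972-11-05"),   # age ~40.0
    mk_patient("C", birth = NA),             # missing age
    mk_patient("D", gender = NA, birth = "1962-11-04"))
  rx <- do.call(rbind, lapply(pats$patient_id, function(id)
    mk_rx(id, "2013-07-10", 90)))
  co <- build_cohort(pats, rx, cfg)
  imp <- impute_missing(co)
  m <- imp$members
  expect_false(anyNA(m$age_years))
  expect_false(anyNA(m$female))
  expect_equal(m$age_years[m$patient_id == "C"],
               mean(co$members$age_years, na.rm = TRUE))
  # binary covariate imputed on its 0/1 encoding: mean of three females = 1
  expect_equal(m$female[m$patient_id == "D"], 1)
  expect_equal(mean(m$age_years), mean(co$members$age_years, na.rm = TRUE))
  expect_equal(m$missing_any, as.numeric(m$patient_id %in% c("C", "D")))

  # no missing values: identity
  co_ok <- build_cohort(pats[1:2, ], rx[1:2, ], cfg)
  expect_equal(impute_missing(co_ok)$members, co_ok$members)
  expect_true(all(impute_missing(co_ok)$members$missing_any == 0))
})

test_that("fractional binary imputation follows the encoded mean", {
  pats <- rbind(mk_patient("A", gender = "female"),
                mk_patient("B", gender = "female"),
                mk_patient("C", gender = "male"),
                mk_patient("D", gender = NA))
  rx <- do.call(rbind, lapply(pats$patient_id, function(id)
    mk_rx(id, "2013-07-10", 90)))
  imp <- impute_missing(build_cohort(pats, rx, cfg))
  expect_equal(imp$members$female[imp$members$patient_id == "D"], 2 / 3)
})

test_that("pre-program coverage is the covered fraction of pre-program window days", {
  p <- mk_patient()
  # fully covered pre-program period
  rx_full <- mk_rx("P1", "2013-01-01", 180)  # window starts at obs_start
  w <- observation_window(p, rx_full, cfg)
  rx_both <- mk_rx_list(c("2013-01-01", "2013-06-28"), c(180, 180))
  dd <- dedup_prescriptions(rx_both)$kept
  w2 <- observation_window(p, dd, cfg)
  cov2 <- daily_coverage(dd, w2, cfg)
  expect_equal(pre_program_coverage(cov2), 1.0)

  # partially covered: window opens 2013-07-26; uncovered until a
  # 30-day prescription on 2013-08-20 -> 20 of 45 pre-program days
  rx_part <- mk_rx_list(c("2013-01-27", "2013-08-20"), c(180, 30))
  w3 <- observation_window(p, rx_part, cfg)
  cov3 <- daily_coverage(rx_part, w3, cfg)
  expect_equal(pre_program_coverage(cov3), 20 / 45)

  # no pre-program observation time
  rx_late <- mk_rx_list(c("2013-04-01", "2013-10-01"), c(180, 90))
  w4 <- observation_window(p, rx_late, cfg)
  expect_equal(w4$start, as.Date("2013-09-28"))
  expect_true(is.na(pre_program_coverage(daily_coverage(rx_late, w4, cfg))))
})

test_that("analysis subsets respect their boundaries", {
  base <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    group = c("Exposed", "Exposed", "Unexposed", "Unknown"),
    pre_program_coverage = c(1.0, 0.97, NA, 0.5),
    art_start_date = as.Date(c("2012-01-01",  # 1.69y before program: recent
                               "2011-09-01",  # > 2y: not recent
                               "2011-09-09",  # 731d before: outside 730.5
                               "2011-09-10")),# 730d before: inside
    stringsAsFactors = FALSE)
  co <- structure(list(members = base,
                       coverage = setNames(vector("list", 4), base$patient_id),
                       config = cfg), class = "cohort")
  low <- select_subset(co, "below_100_baseline")
  expect_setequal(low$members$patient_id, c("B", "D"))  # 1.0 and NA excluded
  rec <- select_subset(co, "recent_initiators")
  expect_setequal(rec$members$patient_id, c("A", "D"))
})

test_that("baseline table uses ANOVA for continuous and chi-squared for categorical", {
  mk_members <- function(n_e, n_u, age_e, age_u, fem_e, fem_u) {
    data.frame(
      patient_id = sprintf("M%03d", seq_len(n_e + n_u)),
      group = rep(c("Exposed", "Unexposed"), c(n_e, n_u)),
      age_years = c(age_e, age_u),
      female = c(fem_e, fem_u),
      art_start_date = as.Date("2011-01-01"),
      transfer_out_date = as.Date(NA),
      window_start = as.Date("2013-07-01"),
      window_end = as.Date("2014-06-26"),
      pre_program_coverage = 0.9,
      missing_any = 0,
      rx_len_first_obs = 180,
      first_line_first_obs = 1,
      fdc_first_obs = 0,
      stringsAsFactors = FALSE)
  }
  co <- function(m) structure(list(members = m, config = cfg), class = "cohort")

  set.seed(5)
  # identical groups: no information, p-values 1
  same <- mk_members(50, 50, rep(30, 50), rep(30, 50),
                     rep(c(0, 1), 25), rep(c(0, 1), 25))
  tb <- baseline_table(co(same))
  expect_equal(tb$p_exposed_vs_unexposed[tb$variable == "Age in years (IQR)"], 1)
  expect_equal(tb$p_exposed_vs_unexposed[tb$variable == "Female"], 1)

  # strongly separated means: F test decisive
  sep <- mk_members(100, 100, rnorm(100, 30, 1), rnorm(100, 50, 1),
                    rbinom(100, 1, 0.5), rbinom(100, 1, 0.9))
  tb2 <- baseline_table(co(sep))
  expect_lt(tb2$p_exposed_vs_unexposed[tb2$variable == "Age in years (IQR)"], 1e-3)
  expect_lt(tb2$p_exposed_vs_unexposed[tb2$variable == "Female"], 1e-3)
})

test_that("exact binomial McNemar on >95% coverage matches closed forms", {
  mk_cov <- function(p_pre, p_dur) {
    pre_n <- 70L; dur_n <- 100L
    data.frame(
      date = seq(as.Date("2013-07-01"), by = "day",
                 length.out = pre_n + dur_n),
      covered = c(rep(TRUE, round(p_pre * pre_n)),
                  rep(FALSE, pre_n - round(p_pre * pre_n)),
                  rep(TRUE, round(p_dur * dur_n)),
                  rep(FALSE, dur_n - round(p_dur * dur_n))),
      period = rep(c("pre_program", "during_program"), c(pre_n, dur_n)),
      stringsAsFactors = FALSE)
  }
  fab_cohort <- function(pairs) {
    ids <- sprintf("Q%02d", seq_along(pairs))
    structure(list(
      members = data.frame(patient_id = ids, stringsAsFactors = FALSE),
      coverage = setNames(lapply(pairs, function(pp) mk_cov(pp[1], pp[2])), ids),
      config = cfg), class = "cohort")
  }
  # 1 vs 7 discordant pairs: p = 2 * P(Binom(8, .5) <= 1)
  pairs <- c(list(c(1, 0.5)), replicate(7, c(0.5, 1), simplify = FALSE),
             replicate(5, c(1, 1), simplify = FALSE))
  mc <- mcnemar_gt95(fab_cohort(pairs))
  expect_equal(unname(mc$estimate), c(1, 7))
  expect_equal(mc$p.value, 2 * pbinom(1, 8, 0.5))

  # all change in the same direction: p = 2 * 0.5^10
  pairs2 <- replicate(10, c(0.5, 1), simplify = FALSE)
  expect_equal(mcnemar_gt95(fab_cohort(pairs2))$p.value, 2 * 0.5^10)

  # no discordant pairs: no information
  pairs3 <- replicate(4, c(1, 1), simplify = FALSE)
  expect_equal(mcnemar_gt95(fab_cohort(pairs3))$p.value, 1)
})
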
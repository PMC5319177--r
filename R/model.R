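# Patient-day dataset assembly, random-intercept logistic model with
# group-by-period interaction, backward elimination, and the translation of
# the program-effect odds ratio into days of coverage per year.

MODEL_CANDIDATES <- c("age_years", "female", "art_duration_30d",
                      "rx_length_30d", "first_line", "fdc", "missing_any")
GROUP_LEVELS <- c("Unexposed", "Exposed", "Unknown")
PERIOD_LEVELS <- c("pre_program", "during_program")

#' Assemble the patient-day analysis dataset
#'
#' Expands every member's coverage series into one row per observed day —
#' the model's unit of observation, so each patient is weighted by their
#' length of observation. Time-varying fields (prior ART duration in
#' 30-day units, active prescription length in 30-day units, regimen line,
#' fixed-dose-combination flag) are read off the coverage-series
#' annotations; patient-level covariates are repeated across the member's
#' rows.
#'
#' @param cohort A [build_cohort()] result with covariates completed (see
#'   [impute_missing()]).
#' @return A data frame with one row per patient-day: `patient_id`,
#'   `covered`, `period`, `group`, `age_years`, `female`,
#'   `art_duration_30d`, `rx_length_30d`, `first_line`, `fdc`,
#'   `missing_any`.
#' @export
build_daily_dataset <- function(cohort) {
  m <- cohort$members
  if (is.null(m) || nrow(m) == 0L) stop("build_daily_dataset: empty cohort")
  pieces <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    cov <- cohort$coverage[[m$patient_id[i]]]
    if (is.null(cov) || nrow(cov) == 0L) {
      stop("build_daily_dataset: member without coverage series: ",
           m$patient_id[i])
    }
    pieces[[i]] <- data.frame(
      patient_id = m$patient_id[i],
      covered = as.integer(cov$covered),
      period = cov$period,
      group = m$group[i],
      age_years = m$age_years[i],
      female = m$female[i],
      art_duration_30d = as.numeric(cov$date - m$art_start_date[i]) / 30,
      rx_length_30d = cov$rx_duration_days / 30,
      first_line = as.numeric(cov$line == "first"),
      fdc = as.numeric(cov$fdc),
      missing_any = m$missing_any[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}

aggregate_rows <- function(rows, vars) {
  key <- do.call(paste, c(rows[c("patient_id", vars)], sep = "\r"))
  y <- rowsum(rows$covered, key, reorder = FALSE)
  n <- rowsum(rep(1L, nrow(rows)), key, reorder = FALSE)
  first <- !duplicated(key)
  agg <- rows[first, c("patient_id", vars), drop = FALSE]
  agg$.y <- as.vector(y)
  agg$.n <- as.vector(n)
  rownames(agg) <- NULL
  agg
}

#' Fit the random-intercept logistic coverage model
#'
#' Fits, by maximum likelihood through [lme4::glmer()], the model
#' \deqn{\mathrm{logit}\,P(covered_{it}=1) = \beta_0 + \gamma_{period}
#'   during_t + \gamma_E Exposed_i + \gamma_U Unknown_i +
#'   \delta_E (Exposed_i \times during_t) + \delta_U (Unknown_i \times
#'   during_t) + \mathbf{x}_{it}'\boldsymbol\beta + u_i,}
#' with \eqn{u_i \sim N(0, \sigma_u^2)} a patient-level random intercept
#' and reference levels group = Unexposed, period = pre-program, so each
#' printed contrast is a single coefficient: \eqn{e^{\delta_E}} is the
#' program effect for the Exposed group. Patient-days with identical
#' covariate values are collapsed into binomial counts before fitting
#' (likelihood-identical, much faster). Wald standard errors, 95%
#' confidence intervals and p-values are reported; non-convergence is
#' flagged on the result, never silently ignored.
#'
#' @param rows A patient-day data frame from [build_daily_dataset()] (or
#'   the model-faithful generator).
#' @param covariates Character vector of candidate covariate columns to
#'   adjust for; group, period and their interaction are always present.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points passed to
#'   `glmer` (1 = Laplace approximation).
#' @return An object of class `coverage_fit`.
#' @export
fit_coverage_model <- function(rows, covariates = MODEL_CANDIDATES,
                               nAGQ = 1L) {
  covariates <- intersect(covariates, names(rows))
  groups_seen <- unique(rows$group)
  if (length(groups_seen) < 2L) {
    stop("fit_coverage_model: need at least 2 exposure groups, got ",
         length(groups_seen))
  }
  if (length(unique(rows$covered)) < 2L) {
    stop("fit_coverage_model: outcome is constant; model is inestimable")
  }
  # drop covariates without variation (inestimable)
  covariates <- covariates[vapply(covariates, function(v)
    stats::var(rows[[v]]) > 0, logical(1))]

  agg <- aggregate_rows(rows, c("period", "group", covariates))
  agg$group <- factor(agg$group, levels = intersect(GROUP_LEVELS, groups_seen))
  agg$period <- factor(agg$period, levels = PERIOD_LEVELS)

  rhs <- paste(c("group * period", covariates, "(1 | patient_id)"),
               collapse = " + ")
  fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~", rhs))
  fit <- lme4::glmer(fml, data = agg, family = stats::binomial(),
                     nAGQ = nAGQ,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- stats::qnorm(0.975)
  tbl <- data.frame(
    term = rownames(sm),
    estimate = est, se = se,
    or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se)),
    row.names = NULL, stringsAsFactors = FALSE)

  vc <- lme4::VarCorr(fit)
  messages <- unlist(fit@optinfo$conv$lme4$messages)
  contr <- function(term) {
    i <- match(term, tbl$term)
    if (is.na(i)) return(NULL)
    stats::setNames(as.numeric(tbl[i, c("or", "ci_low", "ci_high", "p")]),
                    c("or", "ci_low", "ci_high", "p"))
  }
  res <- list(
    fit = fit,
    coefficients = tbl,
    covariates = covariates,
    sigma_u = sqrt(as.numeric(vc$patient_id[1L])),
    contrasts = list(
      OR_during_vs_pre = contr("periodduring_program"),
      OR_pre_Exposed_vs_Unexposed = contr("groupExposed"),
      OR_pre_Unknown_vs_Unexposed = contr("groupUnknown"),
      OR_program_Exposed = contr("groupExposed:periodduring_program"),
      OR_program_Unknown = contr("groupUnknown:periodduring_program")),
    converged = length(messages) == 0L,
    convergence_messages = messages,
    n_patients = length(unique(rows$patient_id)),
    n_days = nrow(rows))
  class(res) <- "coverage_fit"
  res
}

#' @export
print.coverage_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept logistic coverage model (%d patients, %d patient-days)\n",
              x$n_patients, x$n_days))
  cat(sprintf("Random-intercept SD (patient): %.*f\n", digits, x$sigma_u))
  if (!x$converged) {
    cat("NOTE: fit did not cleanly converge:\n")
    cat(paste(" ", x$convergence_messages, collapse = "\n"), "\n")
  }
  tbl <- x$coefficients
  tbl[-1L] <- lapply(tbl[-1L], function(v) signif(v, digits))
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' @export
coef.coverage_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.coverage_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              contrasts = object$contrasts,
              sigma_u = object$sigma_u,
              converged = object$converged,
              n_patients = object$n_patients, n_days = object$n_days)
  class(out) <- "summary.coverage_fit"
  out
}

#' @export
print.summary.coverage_fit <- function(x, ...) {
  cat("Derived group/period contrasts (odds ratios):\n")
  for (nm in names(x$contrasts)) {
    ctr <- x$contrasts[[nm]]
    if (is.null(ctr)) next
    cat(sprintf("  %-28s %.3f (%.3f-%.3f); P = %.4g\n", nm,
                ctr[["or"]], ctr[["ci_low"]], ctr[["ci_high"]], ctr[["p"]]))
  }
  cat(sprintf("Random-intercept SD: %.3f; converged: %s\n",
              x$sigma_u, x$converged))
  invisible(x)
}

#' Stepwise backward elimination of candidate covariates
#'
#' Refits the coverage model repeatedly, at each step removing the single
#' candidate covariate with the largest Wald p-value above the threshold,
#' until every remaining candidate is below it. Group, period and their
#' interaction are retained a priori and are never considered for removal.
#'
#' @param rows Patient-day data frame.
#' @param covariates Starting candidate set.
#' @param p_threshold Retention threshold (default 0.25).
#' @param nAGQ Passed through to [fit_coverage_model()]. The default 0
#'   (lme4's fast PIRLS profiling of the fixed effects) is accurate here
#'   because observation lengths run to hundreds of days per patient; use
#'   1 for a full Laplace fit on smaller datasets.
#' @return A list with `fit` (the final `coverage_fit`), `covariates`
#'   (those retained), and `log` — a data frame recording each removal
#'   with its p-value.
#' @export
backward_eliminate <- function(rows, covariates = MODEL_CANDIDATES,
                               p_threshold = 0.25, nAGQ = 0L) {
  covariates <- intersect(covariates, names(rows))
  log <- data.frame(step = integer(0), removed = character(0),
                    p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_coverage_model(rows, covariates, nAGQ = nAGQ)
    covariates <- fit$covariates  # constant columns drop silently
    cand <- fit$coefficients[match(covariates, fit$coefficients$term), ]
    worst <- which.max(cand$p)
    if (!length(worst) || cand$p[worst] <= p_threshold) break
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, removed = cand$term[worst],
                                 p = cand$p[worst], stringsAsFactors = FALSE))
    covariates <- setdiff(covariates, cand$term[worst])
  }
  list(fit = fit, covariates = covariates, log = log)
}

#' Translate a program-effect odds ratio into days of coverage per year
#'
#' Starting from an observed average daily-coverage probability, divides
#' the coverage odds by the program-effect odds ratio to obtain the
#' hypothetical coverage probability without exposure; the difference in
#' probabilities is the absolute risk reduction, scaled to days per year.
#'
#' @param p_avg Observed average coverage proportion, strictly inside
#'   (0, 1).
#' @param or_effect Program-effect odds ratio (> 0).
#' @param days_per_year Scale factor (default 365.25).
#' @return Days of coverage per year attributable to the exposure
#'   (positive when `or_effect` > 1).
#' @examples
#' coverage_days_gained(0.941, 1.23)  # ~4.6 days per year
#' @export
coverage_days_gained <- function(p_avg, or_effect, days_per_year = 365.25) {
  if (any(p_avg <= 0 | p_avg >= 1)) {
    stop("coverage_days_gained: p_avg must lie strictly inside (0, 1)")
  }
  if (any(or_effect <= 0)) stop("coverage_days_gained: or_effect must be > 0")
  odds <- p_avg / (1 - p_avg)
  odds_hypo <- odds / or_effect
  p_hypo <- odds_hypo / (1 + odds_hypo)
  (p_avg - p_hypo) * days_per_year
}

#' Run the full coverage analysis on a cohort or subset
#'
#' Composes the analysis pipeline: restrict to the requested subset, expand
#' to patient-days, run backward elimination around the a priori
#' group/period terms, and translate the Exposed-group program-effect odds
#' ratio into days of coverage per year using the subset's Exposed
#' during-program mean coverage.
#'
#' @param cohort An imputed [build_cohort()] result.
#' @param subset One of `"full"`, `"below_100_baseline"`,
#'   `"recent_initiators"`.
#' @param covariates Starting candidate covariates for elimination.
#' @param nAGQ Passed to the fitter (see [backward_eliminate()] for the
#'   default).
#' @return An object of class `adherence_analysis` with the final
#'   `coverage_fit`, the elimination log, the Exposed during-program mean
#'   coverage `p_avg`, and `days_gained_per_year`.
#' @export
run_analysis <- function(cohort,
                         subset = c("full", "below_100_baseline",
                                    "recent_initiators"),
                         covariates = MODEL_CANDIDATES, nAGQ = 0L) {
  subset <- match.arg(subset)
  sub <- select_subset(cohort, subset)
  if (is.null(sub$members) || length(unique(sub$members$group)) < 2L) {
    stop("run_analysis: subset '", subset,
         "' has fewer than 2 exposure groups represented")
  }
  rows <- build_daily_dataset(sub)
  elim <- backward_eliminate(rows, covariates,
                             p_threshold = cohort$config$elimination_p,
                             nAGQ = nAGQ)
  fit <- elim$fit
  sel <- rows$group == "Exposed" & rows$period == "during_program"
  p_avg <- if (any(sel)) mean(rows$covered[sel]) else NA_real_
  or_e <- fit$contrasts$OR_program_Exposed
  days <- if (!is.null(or_e) && !is.na(p_avg) && p_avg > 0 && p_avg < 1) {
    coverage_days_gained(p_avg, or_e[["or"]], cohort$config$days_per_year)
  } else NA_real_
  structure(list(subset = subset, fit = fit, elimination = elim$log,
                 covariates = elim$covariates, p_avg = p_avg,
                 days_gained_per_year = days,
                 n_members = nrow(sub$members)),
            class = "adherence_analysis")
}

#' @export
print.adherence_analysis <- function(x, ...) {
  cat(sprintf("Coverage analysis — subset '%s' (n = %d patients)\n",
              x$subset, x$n_members))
  if (nrow(x$elimination)) {
    cat("Backward elimination removed: ",
        paste(sprintf("%s (P=%.3f)", x$elimination$removed, x$elimination$p),
              collapse = ", "), "\n", sep = "")
  } else {
    cat("Backward elimination removed no covariates\n")
  }
  print(summary(x$fit))
  if (!is.na(x$days_gained_per_year)) {
    cat(sprintf("Exposed during-program mean coverage: %.1f%%\n", 100 * x$p_avg))
    cat(sprintf("Program effect: %.1f days of prescription coverage per year\n",
                x$days_gained_per_year))
  }
  invisible(x)
}

#' Table-shaped model report
#'
#' Flattens an [run_analysis()] result into a report table ordered as the
#' published model output: adjusted covariates first, then the period
#' term, the pre-program group contrasts, and the program-effect
#' interactions. Eliminated covariates appear with empty cells.
#'
#' @param analysis An `adherence_analysis` object.
#' @param candidates The full candidate list (for rows of eliminated
#'   terms).
#' @return A data frame with columns `term`, `or`, `ci_low`, `ci_high`,
#'   `p`, `retained`.
#' @export
analysis_report <- function(analysis, candidates = MODEL_CANDIDATES) {
  tbl <- analysis$fit$coefficients
  order_terms <- c(candidates, "periodduring_program", "groupExposed",
                   "groupUnknown", "groupExposed:periodduring_program",
                   "groupUnknown:periodduring_program")
  rows <- lapply(order_terms, function(tm) {
    i <- match(tm, tbl$term)
    if (is.na(i)) {
      data.frame(term = tm, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, retained = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(term = tm, or = tbl$or[i], ci_low = tbl$ci_low[i],
                 ci_high = tbl$ci_high[i], p = tbl$p[i], retained = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
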
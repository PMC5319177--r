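# Coverage engine: prescription deduplication, observation windows, and the
# running-balance construction of day-level prescription coverage.

rx_end <- function(rx) rx$issue_date + rx$duration_days - 1L

check_sorted <- function(rx) {
  if (nrow(rx) > 1L && is.unsorted(as.numeric(rx$issue_date))) {
    stop("prescriptions must be sorted by issue_date")
  }
}

#' Drop re-recorded prescription balances
#'
#' Pharmacy systems sometimes re-record the remaining balance of a long
#' prescription as a fresh record (e.g. a 3-month prescription entered 3
#' months after a 6-month one). A record is treated as a duplicate and
#' dropped when an earlier kept record has the identical agent set and its
#' coverage interval entirely contains the later record's interval.
#'
#' @param rx Data frame of one patient's prescriptions, sorted by
#'   `issue_date`, with columns `issue_date`, `duration_days`, `agents`
#'   (canonical form; see [agents_key()]).
#' @return A list with elements `kept` and `dropped`, which partition the
#'   input rows.
#' @examples
#' rx <- data.frame(issue_date = as.Date(c("2013-01-01", "2013-04-01")),
#'                  duration_days = c(180L, 90L),
#'                  agents = "EFV;FTC;TDF", line = "first", fdc = FALSE)
#' dedup_prescriptions(rx)$dropped$issue_date
#' @export
dedup_prescriptions <- function(rx) {
  check_sorted(rx)
  n <- nrow(rx)
  if (n <= 1L) return(list(kept = rx, dropped = rx[0L, , drop = FALSE]))
  ends <- rx_end(rx)
  keep <- rep(TRUE, n)
  for (i in 2:n) {
    prior <- which(keep[seq_len(i - 1L)])
    contained <- rx$agents[prior] == rx$agents[i] &
      rx$issue_date[i] >= rx$issue_date[prior] &
      ends[i] <= ends[prior]
    if (any(contained)) keep[i] <- FALSE
  }
  list(kept = rx[keep, , drop = FALSE],
       dropped = rx[!keep, , drop = FALSE])
}

#' Determine a patient's observation window
#'
#' Observation begins at the earlier of (a) the day after the end of the
#' patient's first recorded prescription or (b) the day of the second
#' recorded prescription, but never before the observation-period start;
#' it ends at the earlier of transfer-out and the end of pharmacy data.
#'
#' @param patient One row of a validated patients table.
#' @param rx The patient's deduplicated prescriptions, sorted by issue date.
#' @param config A [study_config()].
#' @return An object of class `obs_window` (fields `patient_id`, `start`,
#'   `end`, `has_pre_program_time`), or an object of class `no_obs_window`
#'   when the patient has no observation time; the latter carries a
#'   `reason` field (`"no prescriptions"` or `"no observation time"`).
#' @export
observation_window <- function(patient, rx, config) {
  check_sorted(rx)
  no_window <- function(reason) {
    structure(list(patient_id = patient$patient_id, reason = reason),
              class = "no_obs_window")
  }
  if (nrow(rx) == 0L) return(no_window("no prescriptions"))
  candidate <- rx$issue_date[1L] + rx$duration_days[1L]
  if (nrow(rx) >= 2L) candidate <- min(candidate, rx$issue_date[2L])
  start <- max(config$obs_start, candidate)
  end <- config$data_end
  if (!is.na(patient$transfer_out_date)) {
    end <- min(end, patient$transfer_out_date)
  }
  if (start > end) return(no_window("no observation time"))
  structure(list(patient_id = patient$patient_id, start = start, end = end,
                 has_pre_program_time = start < config$program_start),
            class = "obs_window")
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf("Observation window for %s: %s .. %s (%d days%s)\n",
              x$patient_id, x$start, x$end,
              as.integer(x$end - x$start) + 1L,
              if (x$has_pre_program_time) ", includes pre-program time" else ""))
  invisible(x)
}

# Running balance of coverage days at each prescription issue. At issue k,
# the balance remaining from the previous prescription is capped at
# carryover_cap_days and credited only if the agent set is unchanged;
# a regimen change forfeits the carryover.
issue_balances <- function(rx, cap) {
  n <- nrow(rx)
  bal <- numeric(n)
  bal[1L] <- rx$duration_days[1L]
  if (n > 1L) {
    for (k in 2:n) {
      elapsed <- as.numeric(rx$issue_date[k] - rx$issue_date[k - 1L])
      remaining <- max(bal[k - 1L] - elapsed, 0)
      bal[k] <- if (rx$agents[k] == rx$agents[k - 1L]) {
        min(remaining, cap) + rx$duration_days[k]
      } else {
        rx$duration_days[k]
      }
    }
  }
  bal
}

#' Day-level prescription coverage for one patient
#'
#' Simulates a running balance of coverage days over the patient's
#' deduplicated prescription history (which may begin before the window;
#' history informs the carryover balance): each prescription adds its
#' duration to the capped carried-over remainder when the regimen is
#' unchanged, or resets the balance when the regimen changes; the balance
#' decays one day per calendar day, and a day is covered while the balance
#' is positive. The series is restricted to the observation window and each
#' day is annotated with the period label and the most recently issued
#' prescription's duration, line and fixed-dose-combination flag (carried
#' forward across uncovered gaps).
#'
#' @param rx Deduplicated, sorted prescriptions for one patient.
#' @param window An `obs_window` from [observation_window()].
#' @param config A [study_config()].
#' @return A data frame of class `daily_coverage` with one row per window
#'   day: `date`, `covered` (logical), `period`
#'   (`pre_program`/`during_program`), `rx_duration_days`, `line`, `fdc`;
#'   the patient id is stored in the `"patient_id"` attribute.
#' @export
daily_coverage <- function(rx, window, config) {
  if (is.null(window) || inherits(window, "no_obs_window")) {
    stop("daily_coverage: patient has no observation window")
  }
  check_sorted(rx)
  if (nrow(rx) == 0L) stop("daily_coverage: no prescriptions")
  bal <- issue_balances(rx, config$carryover_cap_days)
  dates <- seq(window$start, window$end, by = "day")
  # most recent issue on or before each date (window start always follows
  # the first issue, by window construction)
  k <- findInterval(as.numeric(dates), as.numeric(rx$issue_date))
  if (any(k == 0L)) stop("daily_coverage: window precedes first prescription")
  since_issue <- as.numeric(dates - rx$issue_date[k])
  covered <- since_issue < bal[k]
  out <- data.frame(
    date = dates,
    covered = covered,
    period = ifelse(dates < config$program_start, "pre_program", "during_program"),
    rx_duration_days = rx$duration_days[k],
    line = rx$line[k],
    fdc = rx$fdc[k],
    stringsAsFactors = FALSE)
  attr(out, "patient_id") <- window$patient_id
  class(out) <- c("daily_coverage", "data.frame")
  out
}

#' Coverage days available from a given date
#'
#' The number of consecutive covered days starting at `date` in a coverage
#' series — e.g. the total supply available to a patient on the day a new
#' prescription is issued, including any carried-over balance.
#'
#' @param coverage A `daily_coverage` series.
#' @param date The first day to count from.
#' @return Integer count of consecutive covered days starting at `date`.
#' @export
coverage_run_length <- function(coverage, date) {
  date <- as.Date(date)
  idx <- which(coverage$date >= date)
  if (!length(idx) || coverage$date[idx[1L]] != date) {
    stop("date not inside the coverage series")
  }
  run <- coverage$covered[idx]
  first_gap <- match(FALSE, run)
  if (is.na(first_gap)) length(run) else first_gap - 1L
}
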
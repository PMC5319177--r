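# In-code fixture builders and the independent per-day inventory oracle.

mk_patient <- function(id = "P1", enrollment = "2012-01-01",
                       birth = "1980-01-01", gender = "female",
                       art_start = "2012-01-15", transfer = NA,
                       status = "available", capture = "2013-06-15",
                       opt_out = NA) {
  data.frame(patient_id = id,
             enrollment_date = as.Date(enrollment),
             birth_date = as.Date(birth),
             gender = gender,
             art_start_date = as.Date(art_start),
             transfer_out_date = as.Date(transfer),
             phone_status = status,
             phone_capture_date = as.Date(capture),
             opt_out_date = as.Date(opt_out),
             stringsAsFactors = FALSE)
}

mk_rx <- function(id = "P1", issue, dur, agents = "EFV;FTC;TDF",
                  line = "first", fdc = FALSE) {
  data.frame(patient_id = id, issue_date = as.Date(issue),
             duration_days = as.integer(dur), agents = agents,
             line = line, fdc = fdc, stringsAsFactors = FALSE)
}

mk_rx_list <- function(issues, durs, agents = "EFV;FTC;TDF", id = "P1") {
  do.call(rbind, Map(function(i, d, a) mk_rx(id, i, d, a),
                     issues, durs,
                     rep_len(agents, length(issues))))
}

# Independent oracle: explicit day-by-day pill inventory from data_start.
# Maintains a scalar balance; each issue caps the carried remainder (same
# regimen) or resets (regimen change); the balance decays daily.
oracle_covered <- function(rx, window, cfg) {
  days <- seq(cfg$data_start, window$end, by = "day")
  covered <- logical(length(days))
  bal <- 0
  prev_agents <- NULL
  for (j in seq_along(days)) {
    d <- days[j]
    for (k in which(rx$issue_date == d)) {
      bal <- if (!is.null(prev_agents) && rx$agents[k] == prev_agents) {
        min(bal, cfg$carryover_cap_days) + rx$duration_days[k]
      } else {
        rx$duration_days[k]
      }
      prev_agents <- rx$agents[k]
    }
    covered[j] <- bal > 0
    bal <- max(bal - 1, 0)
  }
  covered[days >= window$start]
}

random_history <- function(cfg, max_rx = 6L) {
  n <- sample.int(max_rx, 1L)
  issues <- sort(cfg$data_start + sample(0:500, n))
  agent_pool <- c("EFV;FTC;TDF", "3TC;AZT;LPV")
  mk_rx_list(as.character(issues),
             sample(1:180, n, replace = TRUE),
             sample(agent_pool, n, replace = TRUE, prob = c(0.8, 0.2)))
}
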
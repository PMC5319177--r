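# On-disk schemas for the three flat input tables. All dates ISO-8601;
# absent dates are empty strings; agent sets are serialized as
# semicolon-joined, uppercased, sorted drug codes; booleans as true/false.

PATIENT_COLS <- c("patient_id", "enrollment_date", "birth_date", "gender",
                  "art_start_date", "transfer_out_date", "phone_status",
                  "phone_capture_date", "opt_out_date")
RX_COLS <- c("patient_id", "issue_date", "duration_days", "agents", "line",
             "fdc")
EVENT_COLS <- c("patient_id", "event", "event_date")
EVENT_TYPES <- c("intro_sent", "opt_out", "delivery_confirmed")

#' Canonical serialization of an antiretroviral agent set
#'
#' Agent sets are compared as unordered sets of uppercase drug codes, so the
#' canonical text form sorts and uppercases them, joined by ";". The
#' fixed-dose-combination flag is packaging metadata and plays no part in
#' agent-set equality.
#'
#' @param agents Character vector of drug codes (one set) or a
#'   ";"-separated string.
#' @return A single canonical string.
#' @examples
#' agents_key(c("ftc", "TDF", "efv"))
#' @export
agents_key <- function(agents) {
  if (length(agents) == 1L && grepl(";", agents)) {
    agents <- strsplit(agents, ";", fixed = TRUE)[[1]]
  }
  agents <- toupper(trimws(agents))
  agents <- agents[nzchar(agents)]
  paste(sort(unique(agents)), collapse = ";")
}

parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  present <- !is.na(x) & nzchar(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[present])
  d <- as.Date(rep(NA_character_, sum(present)))
  d[ok] <- as.Date(x[present][ok], format = "%Y-%m-%d")
  out[present] <- d
  attr(out, "malformed") <- which(present)[!ok | is.na(d)]
  out
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
fmt_bool <- function(b) ifelse(b, "true", "false")

read_raw_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(raw), cols)) {
    stop(sprintf("header of %s must be exactly: %s (got: %s)",
                 path, paste(cols, collapse = ","),
                 paste(names(raw), collapse = ",")))
  }
  raw
}

collect_date <- function(raw, col, problems) {
  d <- parse_iso_date(raw[[col]])
  for (i in attr(d, "malformed")) {
    problems$add(i, sprintf("malformed %s '%s'", col, raw[[col]][i]))
  }
  attr(d, "malformed") <- NULL
  d
}

make_problems <- function() {
  rows <- integer(0); reasons <- character(0)
  list(
    add = function(row, reason) {
      rows <<- c(rows, row); reasons <<- c(reasons, reason)
    },
    get = function() data.frame(row = rows, reason = reasons,
                                stringsAsFactors = FALSE)
  )
}

finish_read <- function(records, problems, strict, what) {
  bad <- problems$get()
  if (nrow(bad) && strict) {
    msg <- paste(sprintf("row %d: %s", bad$row, bad$reason), collapse = "\n  ")
    stop(sprintf("%s validation failed:\n  %s", what, msg))
  }
  keep <- !(seq_len(nrow(records)) %in% unique(bad$row))
  accepted <- records[keep, , drop = FALSE]
  rownames(accepted) <- NULL
  structure(accepted, rejected = bad)
}

#' Read and validate the patients table
#'
#' @param path Path to a patients CSV with columns
#'   `patient_id, enrollment_date, birth_date, gender, art_start_date,
#'   transfer_out_date, phone_status, phone_capture_date, opt_out_date`.
#' @param strict If `TRUE` (default) any invalid row is an error naming the
#'   offending rows; if `FALSE`, invalid rows are dropped and returned in
#'   the `"rejected"` attribute (a data frame of row numbers and reasons).
#' @return A data frame of validated patient records with `Date` columns.
#' @export
read_patients <- function(path, strict = TRUE) {
  raw <- read_raw_csv(path, PATIENT_COLS)
  pr <- make_problems()
  n <- nrow(raw)

  dat <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (col in c("enrollment_date", "birth_date", "art_start_date",
                "transfer_out_date", "phone_capture_date", "opt_out_date")) {
    dat[[col]] <- collect_date(raw, col, pr)
  }
  dat$gender <- ifelse(nzchar(raw$gender), raw$gender, NA_character_)
  dat$phone_status <- raw$phone_status

  for (i in seq_len(n)) {
    if (!nzchar(dat$patient_id[i])) pr$add(i, "empty patient_id")
    g <- dat$gender[i]
    if (!is.na(g) && !g %in% c("female", "male")) {
      pr$add(i, sprintf("unknown gender code '%s'", g))
    }
    if (!dat$phone_status[i] %in% c("available", "absent", "unknown")) {
      pr$add(i, sprintf("unknown phone_status '%s'", dat$phone_status[i]))
    }
    if (is.na(dat$enrollment_date[i])) pr$add(i, "missing enrollment_date")
    if (is.na(dat$art_start_date[i])) pr$add(i, "missing art_start_date")
    if (!is.na(dat$birth_date[i]) && !is.na(dat$art_start_date[i]) &&
        dat$art_start_date[i] < dat$birth_date[i]) {
      pr$add(i, "art_start_date precedes birth_date")
    }
    if (!is.na(dat$transfer_out_date[i]) && !is.na(dat$enrollment_date[i]) &&
        dat$transfer_out_date[i] < dat$enrollment_date[i]) {
      pr$add(i, "transfer_out_date precedes enrollment_date")
    }
    if (identical(dat$phone_status[i], "available") &&
        is.na(dat$phone_capture_date[i])) {
      pr$add(i, "phone_status 'available' without phone_capture_date")
    }
  }
  dup <- duplicated(dat$patient_id)
  for (i in which(dup)) pr$add(i, sprintf("duplicate patient_id '%s'", dat$patient_id[i]))

  dat <- dat[, PATIENT_COLS]
  finish_read(dat, pr, strict, "patients")
}

#' Read and validate the prescriptions table
#'
#' @param path Path to a prescriptions CSV with columns
#'   `patient_id, issue_date, duration_days, agents, line, fdc`.
#' @inheritParams read_patients
#' @return A data frame of validated prescription records, sorted by
#'   `(patient_id, issue_date)`, with `agents` in canonical form.
#' @export
read_prescriptions <- function(path, strict = TRUE) {
  raw <- read_raw_csv(path, RX_COLS)
  pr <- make_problems()
  n <- nrow(raw)

  dat <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  dat$issue_date <- collect_date(raw, "issue_date", pr)
  dur <- suppressWarnings(as.integer(raw$duration_days))
  dat$duration_days <- dur
  dat$agents <- vapply(raw$agents, agents_key, character(1), USE.NAMES = FALSE)
  dat$line <- raw$line
  fdc <- rep(NA, n)
  fdc[raw$fdc %in% c("true", "TRUE", "1")] <- TRUE
  fdc[raw$fdc %in% c("false", "FALSE", "0")] <- FALSE
  dat$fdc <- fdc

  for (i in seq_len(n)) {
    if (!nzchar(dat$patient_id[i])) pr$add(i, "empty patient_id")
    if (is.na(dat$issue_date[i])) pr$add(i, "missing issue_date")
    if (is.na(dur[i]) || dur[i] < 1L || dur[i] > 186L) {
      pr$add(i, sprintf("duration_days '%s' outside [1, 186]", raw$duration_days[i]))
    }
    if (!nzchar(dat$agents[i])) pr$add(i, "empty agent set")
    if (!dat$line[i] %in% c("first", "second")) {
      pr$add(i, sprintf("unknown line code '%s'", dat$line[i]))
    }
    if (is.na(fdc[i])) pr$add(i, sprintf("unparseable fdc '%s'", raw$fdc[i]))
  }

  out <- finish_read(dat, pr, strict, "prescriptions")
  rej <- attr(out, "rejected")
  out <- out[order(out$patient_id, out$issue_date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Read and validate the program-events table
#'
#' @param path Path to an events CSV with columns
#'   `patient_id, event, event_date`; `event` is one of `intro_sent`,
#'   `opt_out`, `delivery_confirmed`.
#' @inheritParams read_patients
#' @return A validated data frame of program events.
#' @export
read_events <- function(path, strict = TRUE) {
  raw <- read_raw_csv(path, EVENT_COLS)
  pr <- make_problems()
  dat <- data.frame(patient_id = raw$patient_id,
                    event = raw$event, stringsAsFactors = FALSE)
  dat$event_date <- collect_date(raw, "event_date", pr)
  for (i in seq_len(nrow(raw))) {
    if (!dat$event[i] %in% EVENT_TYPES) {
      pr$add(i, sprintf("unknown event type '%s'", dat$event[i]))
    }
    if (is.na(dat$event_date[i])) pr$add(i, "missing event_date")
  }
  finish_read(dat[, EVENT_COLS], pr, strict, "events")
}

#' Read the three clinic input tables
#'
#' Convenience wrapper that reads and validates patients, prescriptions and
#' (optionally) program events. Opt-out dates found in the events table are
#' merged into the patient records when the patients file leaves them blank
#' (group assignment is intention-to-treat, so opt-out is descriptive only).
#'
#' @param patients,prescriptions,events File paths; `events` may be `NULL`.
#' @param strict Passed to the individual readers.
#' @return A list with elements `patients`, `prescriptions`, `events`.
#' @export
read_tables <- function(patients, prescriptions, events = NULL,
                        strict = TRUE) {
  pat <- read_patients(patients, strict = strict)
  rx <- read_prescriptions(prescriptions, strict = strict)
  ev <- if (is.null(events)) NULL else read_events(events, strict = strict)
  orphan <- setdiff(rx$patient_id, pat$patient_id)
  if (length(orphan) && strict) {
    stop("prescriptions reference unknown patient_id: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  if (!is.null(ev)) {
    oo <- ev[ev$event == "opt_out", ]
    idx <- match(pat$patient_id, oo$patient_id)
    fill <- is.na(pat$opt_out_date) & !is.na(idx)
    pat$opt_out_date[fill] <- oo$event_date[idx[fill]]
  }
  list(patients = pat, prescriptions = rx, events = ev)
}

write_canonical_csv <- function(dat, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(dat), collapse = ","), con, sep = "\n")
  if (nrow(dat)) {
    body <- do.call(paste, c(unname(dat), sep = ","))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Write clinic tables in canonical CSV form
#'
#' Writers are inverse to the readers: `read_*()` on the written file
#' reproduces the in-memory table, and writing again is byte-identical
#' (dates ISO-8601, absent values empty, agents canonical, booleans
#' lowercase).
#'
#' @param patients,prescriptions,events Validated data frames as returned by
#'   the corresponding readers (or the generator).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_patients <- function(patients, path) {
  out <- data.frame(
    patient_id = patients$patient_id,
    enrollment_date = fmt_date(patients$enrollment_date),
    birth_date = fmt_date(patients$birth_date),
    gender = ifelse(is.na(patients$gender), "", patients$gender),
    art_start_date = fmt_date(patients$art_start_date),
    transfer_out_date = fmt_date(patients$transfer_out_date),
    phone_status = patients$phone_status,
    phone_capture_date = fmt_date(patients$phone_capture_date),
    opt_out_date = fmt_date(patients$opt_out_date),
    stringsAsFactors = FALSE)
  write_canonical_csv(out, path)
}

#' @rdname write_patients
#' @export
write_prescriptions <- function(prescriptions, path) {
  ord <- order(prescriptions$patient_id, prescriptions$issue_date)
  prescriptions <- prescriptions[ord, , drop = FALSE]
  out <- data.frame(
    patient_id = prescriptions$patient_id,
    issue_date = fmt_date(prescriptions$issue_date),
    duration_days = as.integer(prescriptions$duration_days),
    agents = vapply(prescriptions$agents, agents_key, character(1),
                    USE.NAMES = FALSE),
    line = prescriptions$line,
    fdc = fmt_bool(prescriptions$fdc),
    stringsAsFactors = FALSE)
  write_canonical_csv(out, path)
}

#' @rdname write_patients
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    patient_id = events$patient_id,
    event = events$event,
    event_date = fmt_date(events$event_date),
    stringsAsFactors = FALSE)
  write_canonical_csv(out, path)
}
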
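#' @name registry
#' @title Registry input/output and cleaning
#'
#' @description
#' The registry is a flat UTF-8 CSV, one row per operated hip-fracture
#' patient, with a header row, ISO-8601 timestamps (local clock time, no
#' timezone arithmetic) and empty cells for missing values. The column
#' dictionary ships at \code{system.file("extdata", "registry_columns.csv",
#' package = "tpaudit")}.
NULL

registry_spec <- function() {
  list(
    character = c("patient_id", "hospital_id", "complication_types"),
    integer   = c("age_years", "katz6_adl"),
    logical   = c("pathologic_fracture", "periprosthetic_fracture"),
    timestamp = c("ed_arrival", "surgery_start", "discharge"),
    category  = list(
      sex = c("female", "male"),
      asa_class = c("asa12", "asa34"),
      dementia = c("no", "yes", "unknown"),
      living_situation = c("independent", "institutionalized"),
      fracture_type = c("fn_nondisplaced", "fn_displaced", "a1", "a2", "a3",
                        "subtrochanteric"),
      treatment = c("osteosynthesis", "prosthesis"),
      malnutrition_assessed = c("met", "not_met"),
      orthogeriatric_management = c("met", "not_met"),
      certified_surgeon = c("met", "not_met"),
      complication_any = c("yes", "no"),
      in_hospital_death = c("yes", "no")
    )
  )
}

#' Registry column names
#'
#' @return character vector of the documented registry CSV columns, in file
#'   order.
#' @export
registry_columns <- function() {
  c("patient_id", "hospital_id", "age_years", "sex", "asa_class", "dementia",
    "katz6_adl", "living_situation", "fracture_type", "pathologic_fracture",
    "periprosthetic_fracture", "treatment", "ed_arrival", "surgery_start",
    "discharge", "malnutrition_assessed", "orthogeriatric_management",
    "certified_surgeon", "complication_any", "complication_types",
    "in_hospital_death")
}

parse_ts <- function(x) {
  x <- as.character(x)
  x[x == ""] <- NA_character_
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  # fall back to space-separated and date-only forms
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d", tz = "UTC")
  }
  out
}

format_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

#' Read a patient registry CSV
#'
#' Parses the documented CSV dialect into a typed patient table, logging every
#' data problem as a row-addressed issue instead of dropping rows. Unknown
#' category strings, out-of-range Katz-6 ADL scores and unparseable timestamps
#' are coerced to missing with a logged issue; a timestamp pair violating
#' chronology (surgery before arrival, discharge before surgery) has the later
#' timestamp coded missing so the record fails eligibility explicitly rather
#' than silently.
#'
#' @param source path to a CSV file (or a connection readable by
#'   \code{read.csv}).
#' @param config an \code{\link{analysis_config}} object.
#' @return a list with components \code{records} (data.frame, one row per
#'   registry row) and \code{issues} (data.frame with columns \code{row},
#'   \code{column}, \code{reason}).
#' @export
parse_registry <- function(source, config = analysis_config()) {
  assert_config(config)
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(registry_columns(), names(raw))
  if (length(missing_cols)) {
    stop_tp("registry is missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  raw <- raw[registry_columns()]
  n <- nrow(raw)
  issues <- list()
  log_issue <- function(rows, column, reason) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = rows, column = column, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  spec <- registry_spec()
  rec <- data.frame(patient_id = raw$patient_id,
                    hospital_id = raw$hospital_id,
                    stringsAsFactors = FALSE)

  for (col in spec$integer) {
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.integer(x))
    bad <- !is.na(x) & is.na(v)
    log_issue(which(bad), col, "not an integer; set to missing")
    if (col == "katz6_adl") {
      oob <- !is.na(v) & (v < 0L | v > 6L)
      log_issue(which(oob), col, "outside 0-6; set to missing")
      v[oob] <- NA_integer_
    }
    if (col == "age_years") {
      neg <- !is.na(v) & v < 0L
      log_issue(which(neg), col, "negative age; set to missing")
      v[neg] <- NA_integer_
    }
    rec[[col]] <- v
  }

  for (col in spec$logical) {
    x <- tolower(raw[[col]])
    v <- rep(NA, n)
    v[x %in% c("true", "t", "1", "yes")] <- TRUE
    v[x %in% c("false", "f", "0", "no", "")] <- FALSE
    bad <- is.na(v) & !(x == "")
    log_issue(which(bad), col, "unrecognised boolean; set to false")
    v[is.na(v)] <- FALSE
    rec[[col]] <- v
  }

  for (col in names(spec$category)) {
    levs <- spec$category[[col]]
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    bad <- !is.na(x) & !(x %in% levs)
    log_issue(which(bad), col,
              paste0("unknown category '", x[bad], "'; set to missing"))
    x[bad] <- NA_character_
    rec[[col]] <- factor(x, levels = levs)
  }

  for (col in spec$timestamp) {
    x <- raw[[col]]
    v <- parse_ts(x)
    bad <- is.na(v) & !(x == "")
    log_issue(which(bad), col, "unparseable timestamp; set to missing")
    rec[[col]] <- v
  }

  # chronology: code the later timestamp missing so eligibility/cleaning
  # handles the record explicitly
  neg_surg <- !is.na(rec$ed_arrival) & !is.na(rec$surgery_start) &
    rec$surgery_start < rec$ed_arrival
  log_issue(which(neg_surg), "surgery_start",
            "before ed_arrival; set to missing")
  rec$surgery_start[neg_surg] <- as.POSIXct(NA)
  neg_dis <- !is.na(rec$surgery_start) & !is.na(rec$discharge) &
    rec$discharge < rec$surgery_start
  log_issue(which(neg_dis), "discharge",
            "before surgery_start; set to missing")
  rec$discharge[neg_dis] <- as.POSIXct(NA)

  # complication bookkeeping: a recorded subtype implies an event
  types <- raw$complication_types
  types[is.na(types)] <- ""
  rec$complication_types <- types
  has_type <- types != ""
  contradict <- has_type &
    (is.na(rec$complication_any) | rec$complication_any != "yes")
  log_issue(which(contradict), "complication_any",
            "subtype recorded; forced to yes")
  rec$complication_any[contradict] <- "yes"

  rec <- rec[registry_columns()]
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(), reason = character(),
               stringsAsFactors = FALSE)
  issues <- issues[order(issues$row), , drop = FALSE]
  rownames(issues) <- NULL
  list(records = rec, issues = issues)
}

#' Write a patient registry CSV
#'
#' Inverse of \code{\link{parse_registry}}: writes the documented dialect
#' (ISO-8601 timestamps, empty cell = missing) so that
#' \code{parse_registry(write_registry(x))} reproduces \code{x} field by
#' field.
#'
#' @param records a typed patient table as returned by
#'   \code{parse_registry()$records} or \code{\link{generate_registry}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(records, path) {
  out <- records[registry_columns()]
  for (col in registry_spec()$timestamp) out[[col]] <- format_ts(out[[col]])
  for (col in registry_spec()$logical) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive time intervals from the registry timestamps
#'
#' @param records patient table with \code{ed_arrival}, \code{surgery_start},
#'   \code{discharge} timestamp columns.
#' @return data.frame with \code{time_to_surgery_hours} (arrival to surgery,
#'   fractional hours), \code{postop_stay_days} (surgery to discharge,
#'   fractional days) and \code{total_stay_days} (arrival to discharge); an
#'   interval is \code{NA} whenever either endpoint is missing.
#' @export
derive_intervals <- function(records) {
  tts <- as.numeric(difftime(records$surgery_start, records$ed_arrival,
                             units = "hours"))
  postop <- as.numeric(difftime(records$discharge, records$surgery_start,
                                units = "days"))
  total <- as.numeric(difftime(records$discharge, records$ed_arrival,
                               units = "days"))
  if (any(tts < 0, na.rm = TRUE) || any(postop < 0, na.rm = TRUE)) {
    stop_tp("negative interval: timestamps violate chronology; ",
            "run parse_registry() so chronology violations are coded missing")
  }
  data.frame(time_to_surgery_hours = tts,
             postop_stay_days = postop,
             total_stay_days = total)
}

#' Apply the data-entry-error caps
#'
#' Derives the time intervals and codes as missing a time to surgery beyond
#' the 2-week cap and a hospital stay beyond the 1-year cap, which the audit
#' treats as data-entry errors. Timestamps themselves are retained; the
#' capped intervals are flagged. Idempotent: cleaning a cleaned table changes
#' nothing.
#'
#' @param records patient table.
#' @param config an \code{\link{analysis_config}}.
#' @return the table with derived columns \code{time_to_surgery_hours},
#'   \code{postop_stay_days}, \code{total_stay_days} and logical flags
#'   \code{tts_capped}, \code{los_capped}.
#' @export
clean_records <- function(records, config = analysis_config()) {
  assert_config(config)
  iv <- derive_intervals(records)
  tts_capped <- !is.na(iv$time_to_surgery_hours) &
    iv$time_to_surgery_hours > config$tts_cap_hours
  iv$time_to_surgery_hours[tts_capped] <- NA_real_
  los_capped <- !is.na(iv$total_stay_days) &
    iv$total_stay_days > config$los_cap_days
  iv$postop_stay_days[los_capped] <- NA_real_
  iv$total_stay_days[los_capped] <- NA_real_
  records$time_to_surgery_hours <- iv$time_to_surgery_hours
  records$postop_stay_days <- iv$postop_stay_days
  records$total_stay_days <- iv$total_stay_days
  records$tts_capped <- tts_capped
  records$los_capped <- los_capped
  records
}

eligibility_rules <- function() {
  c("age", "window", "pathologic", "periprosthetic", "mandatory")
}

#' Select the eligible cohort
#'
#' Retains patients at or above the minimum age, operated within the surgery
#' window, without a pathologic or periprosthetic fracture, and with the
#' mandatory minimum of recorded items (age, emergency-department arrival and
#' surgery timestamps). A record failing several rules is tallied once, under
#' the first failing rule in the fixed order age, window, pathologic,
#' periprosthetic, mandatory; a missing age or surgery date is tallied under
#' \code{mandatory}, since the age and window rules cannot be assessed.
#'
#' @param records cleaned patient table (see \code{\link{clean_records}}).
#' @param config an \code{\link{analysis_config}}.
#' @return list with \code{records} (the eligible subset), \code{tally}
#'   (named integer vector of exclusion counts per rule, in rule order) and
#'   \code{excluded} (data.frame of \code{patient_id}, \code{reason}).
#' @export
select_eligible <- function(records, config = analysis_config()) {
  assert_config(config)
  n <- nrow(records)
  surg_date <- as.Date(records$surgery_start, tz = "UTC")
  fails <- cbind(
    age = !is.na(records$age_years) &
      records$age_years < config$eligibility_min_age,
    window = !is.na(surg_date) &
      (surg_date < config$surgery_window[1] |
         surg_date > config$surgery_window[2]),
    pathologic = records$pathologic_fracture %in% TRUE,
    periprosthetic = records$periprosthetic_fracture %in% TRUE,
    mandatory = is.na(records$age_years) | is.na(records$ed_arrival) |
      is.na(records$surgery_start)
  )
  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1L] else NA_integer_
  })
  excluded <- !is.na(first_fail)
  reason <- eligibility_rules()[first_fail[excluded]]
  tally <- table(factor(reason, levels = eligibility_rules()))
  tally <- stats::setNames(as.integer(tally), eligibility_rules())
  list(
    records = records[!excluded, , drop = FALSE],
    tally = tally,
    excluded = data.frame(
      patient_id = records$patient_id[excluded],
      reason = reason,
      stringsAsFactors = FALSE)
  )
}
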
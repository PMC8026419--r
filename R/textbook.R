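#' Score the four process indicators
#'
#' Evaluates, per patient, the four textbook-process indicators as tri-states
#' (\code{met} / \code{not_met} / \code{NA} = missing). Assessment of
#' malnutrition, orthogeriatric management and certified-surgeon operation
#' pass through the recorded registry tri-states; the surgery-within-24h
#' indicator is derived from the cleaned time to surgery, met iff the elapsed
#' time is at or below the cutoff (inclusive boundary), and missing whenever
#' the derived interval is missing (including the data-entry-error cap).
#'
#' @param records cleaned, eligible patient table (needs
#'   \code{time_to_surgery_hours}; run \code{\link{clean_records}} first).
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame with \code{patient_id}, \code{hospital_id} and one
#'   factor column per indicator (levels \code{met}, \code{not_met}; missing
#'   as \code{NA}).
#' @export
evaluate_indicators <- function(records, config = analysis_config()) {
  assert_config(config)
  if (is.null(records$time_to_surgery_hours)) {
    stop_tp("records carry no `time_to_surgery_hours`; run clean_records() first")
  }
  tts <- records$time_to_surgery_hours
  s24 <- ifelse(is.na(tts), NA_character_,
                ifelse(tts <= config$tts_indicator_cutoff_hours,
                       "met", "not_met"))
  data.frame(
    patient_id = records$patient_id,
    hospital_id = records$hospital_id,
    malnutrition = as_tristate(records$malnutrition_assessed),
    surgery_within_24h = as_tristate(s24),
    orthogeriatric = as_tristate(records$orthogeriatric_management),
    certified_surgeon = as_tristate(records$certified_surgeon),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the all-or-none textbook-process composite
#'
#' A patient received textbook-process care iff all four indicators are met.
#' One or more indicators not met, or missing data on any of them, places the
#' patient in the non-textbook group; failed and missing indicators are
#' listed separately so the bookkeeping (textbook + failed-only +
#' missing-involved = n) stays auditable.
#'
#' @param status indicator table from \code{\link{evaluate_indicators}}.
#' @return data.frame with \code{patient_id}, \code{hospital_id},
#'   \code{textbook} (logical), \code{failed} and \code{missing}
#'   (semicolon-separated indicator names, \code{""} when none).
#' @export
evaluate_textbook_process <- function(status) {
  ind <- tp_indicators()
  m <- sapply(ind, function(i) as.character(status[[i]]))
  if (nrow(status) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, ind))
  failed <- apply(m, 1L, function(r)
    paste(ind[!is.na(r) & r == "not_met"], collapse = ";"))
  missing <- apply(m, 1L, function(r) paste(ind[is.na(r)], collapse = ";"))
  data.frame(
    patient_id = status$patient_id,
    hospital_id = status$hospital_id,
    textbook = failed == "" & missing == "",
    failed = failed,
    missing = missing,
    stringsAsFactors = FALSE
  )
}

#' Score a cleaned cohort for textbook process
#'
#' Convenience wrapper: evaluates the indicators and the composite and binds
#' the results onto the patient table.
#'
#' @inheritParams evaluate_indicators
#' @return the patient table with the four indicator columns plus
#'   \code{textbook}, \code{failed}, \code{missing} appended.
#' @export
score_textbook <- function(records, config = analysis_config()) {
  status <- evaluate_indicators(records, config)
  tp <- evaluate_textbook_process(status)
  cbind(records,
        status[tp_indicators()],
        tp[c("textbook", "failed", "missing")])
}

#' Per-hospital and overall textbook-process compliance
#'
#' @param results composite results (from
#'   \code{\link{evaluate_textbook_process}} or a scored table) with
#'   \code{hospital_id} and \code{textbook} columns.
#' @param config an \code{\link{analysis_config}} (controls percentage
#'   rounding).
#' @return data.frame with one row per hospital plus an \code{"overall"} row:
#'   \code{stratum}, \code{n}, \code{textbook} (count), \code{rate_percent}
#'   (rounded; \code{NA} for an empty stratum).
#' @export
compliance_summary <- function(results, config = analysis_config()) {
  assert_config(config)
  strat <- function(ids, label) {
    keep <- results$hospital_id %in% ids
    n <- sum(keep)
    k <- sum(results$textbook[keep])
    data.frame(stratum = label, n = n, textbook = k,
               rate_percent = if (n > 0)
                 round_half_up(100 * k / n, config$round_percent)
               else NA_real_,
               stringsAsFactors = FALSE)
  }
  hospitals <- sort(unique(results$hospital_id))
  out <- do.call(rbind, lapply(hospitals, function(h) strat(h, h)))
  rbind(strat(hospitals, "overall"), out)
}

#' Cumulative compliance funnel
#'
#' Computes, per stratum (overall and per hospital), how many patients remain
#' after each indicator in sequence: step k counts patients with indicators
#' 1..k all met, a missing indicator dropping the patient at that step. The
#' final step therefore equals the textbook-process count regardless of the
#' order chosen, while intermediate bars depend on it.
#'
#' @param status indicator table from \code{\link{evaluate_indicators}}.
#' @param config an \code{\link{analysis_config}}; \code{config$funnel_order}
#'   sets the indicator sequence.
#' @return long-format data.frame (class \code{tp_funnel}): \code{stratum},
#'   \code{step}, \code{indicator}, \code{survivors},
#'   \code{percent} (of the stratum's eligible n), ready for CSV export and
#'   re-plotting.
#' @export
cumulative_funnel <- function(status, config = analysis_config()) {
  assert_config(config)
  order <- config$funnel_order
  if (!setequal(order, tp_indicators()) ||
      length(order) != length(tp_indicators())) {
    stop_tp("funnel order must be a permutation of the four indicators")
  }
  strata <- c(list(overall = unique(status$hospital_id)),
              stats::setNames(as.list(sort(unique(status$hospital_id))),
                              sort(unique(status$hospital_id))))
  rows <- lapply(names(strata), function(label) {
    sub <- status[status$hospital_id %in% strata[[label]], , drop = FALSE]
    n <- nrow(sub)
    surviving <- rep(TRUE, n)
    do.call(rbind, lapply(seq_along(order), function(k) {
      ik <- sub[[order[k]]]
      surviving <<- surviving & !is.na(ik) & ik == "met"
      data.frame(stratum = label, step = k, indicator = order[k],
                 survivors = sum(surviving),
                 percent = if (n > 0)
                   round_half_up(100 * sum(surviving) / n,
                                 config$round_percent)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tp_funnel", class(out))
  out
}

#' Composite bookkeeping reconciliation
#'
#' Partitions a scored cohort into textbook patients, non-textbook patients
#' whose indicators were all observed (failed-only), and patients with at
#' least one missing indicator. The three counts always sum to n.
#'
#' @param results composite results with \code{textbook}, \code{failed},
#'   \code{missing} columns.
#' @return named integer vector \code{c(textbook, failed_only,
#'   missing_involved, n)}.
#' @export
tp_bookkeeping <- function(results) {
  textbook <- sum(results$textbook)
  missing_involved <- sum(results$missing != "")
  failed_only <- sum(!results$textbook & results$missing == "")
  c(textbook = textbook, failed_only = failed_only,
    missing_involved = missing_involved, n = nrow(results))
}
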
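#' Analysis configuration
#'
#' Bundles every tunable constant of the audit pipeline. Defaults follow the
#' study conventions for elderly hip-fracture audits: patients aged 70+,
#' surgery in the 2018 calendar year, a 2-week time-to-surgery / 1-year
#' length-of-stay data-entry-error cap, the 24-hour surgery indicator cutoff,
#' prolonged stay at >= 6 post-operative days, univariable screening at
#' p < 0.10 and significance at p < 0.05.
#'
#' @param eligibility_min_age minimum age in completed years at surgery.
#' @param surgery_window length-2 Date vector; surgery dates outside it are
#'   ineligible.
#' @param tts_cap_hours time-to-surgery beyond this is treated as a data-entry
#'   error and coded missing (hours).
#' @param los_cap_days total stay beyond this is treated as a data-entry error
#'   and coded missing (days).
#' @param tts_indicator_cutoff_hours the "surgery within 24 h" indicator is
#'   met iff time to surgery is at or below this cutoff (inclusive).
#' @param prolonged_los_cutoff_days prolonged stay is a post-operative stay of
#'   at least this many days (inclusive).
#' @param screening_alpha p-value threshold for univariable covariate
#'   screening.
#' @param significance_alpha p-value threshold for statistical significance.
#' @param z_value standard-normal quantile used for all Wald and O/E
#'   intervals.
#' @param missing_category_threshold if a variable's missing fraction is below
#'   this, missing patients are dropped from that variable's test/model;
#'   otherwise missing is kept as an explicit level.
#' @param epv_minimum minimum events per model parameter required before a
#'   multivariable model is attempted (mortality feasibility rule).
#' @param round_ratios decimal places for reported odds and O/E ratios.
#' @param round_percent decimal places for reported percentages.
#' @param funnel_order indicator order used for the cumulative funnel.
#' @param expected_prediction prediction set for expected counts:
#'   \code{"complete_cases"} (the model's fitting set, default) or
#'   \code{"all_imputed"} (every scored patient, missing covariates imputed by
#'   mode/median).
#' @param haldane if TRUE, apply the Haldane-Anscombe 0.5 correction to 2x2
#'   tables containing a zero cell; default FALSE (CI flagged unavailable).
#'
#' @return an object of class \code{tp_config} (a named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$tts_indicator_cutoff_hours
analysis_config <- function(eligibility_min_age = 70,
                            surgery_window = as.Date(c("2018-01-01", "2018-12-31")),
                            tts_cap_hours = 336,
                            los_cap_days = 365,
                            tts_indicator_cutoff_hours = 24,
                            prolonged_los_cutoff_days = 6,
                            screening_alpha = 0.10,
                            significance_alpha = 0.05,
                            z_value = 1.96,
                            missing_category_threshold = 0.05,
                            epv_minimum = 10,
                            round_ratios = 2,
                            round_percent = 1,
                            funnel_order = c("malnutrition", "surgery_within_24h",
                                             "orthogeriatric", "certified_surgeon"),
                            expected_prediction = c("complete_cases", "all_imputed"),
                            haldane = FALSE) {
  expected_prediction <- match.arg(expected_prediction)
  stopifnot(
    eligibility_min_age > 0, tts_cap_hours > 0, los_cap_days > 0,
    tts_indicator_cutoff_hours > 0, prolonged_los_cutoff_days > 0,
    screening_alpha > 0, significance_alpha > 0,
    screening_alpha > significance_alpha,
    z_value >= 0, missing_category_threshold > 0, epv_minimum > 0,
    length(surgery_window) == 2, !anyNA(surgery_window)
  )
  if (!setequal(funnel_order, tp_indicators())) {
    stop("`funnel_order` must be a permutation of: ",
         paste(tp_indicators(), collapse = ", "), call. = FALSE)
  }
  structure(list(
    eligibility_min_age = eligibility_min_age,
    surgery_window = as.Date(surgery_window),
    tts_cap_hours = tts_cap_hours,
    los_cap_days = los_cap_days,
    tts_indicator_cutoff_hours = tts_indicator_cutoff_hours,
    prolonged_los_cutoff_days = prolonged_los_cutoff_days,
    screening_alpha = screening_alpha,
    significance_alpha = significance_alpha,
    z_value = z_value,
    missing_category_threshold = missing_category_threshold,
    epv_minimum = epv_minimum,
    round_ratios = round_ratios,
    round_percent = round_percent,
    funnel_order = funnel_order,
    expected_prediction = expected_prediction,
    haldane = haldane
  ), class = "tp_config")
}

#' The four textbook-process indicator names
#'
#' @return character vector of the indicator column names, in canonical order.
#' @export
tp_indicators <- function() {
  c("malnutrition", "surgery_within_24h", "orthogeriatric", "certified_surgeon")
}
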
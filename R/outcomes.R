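#' Baseline comparison of textbook vs non-textbook patients
#'
#' Renders, per case-mix variable, the overall and per-group summaries
#' (counts as "n (percent)", age as "mean (SD)", Katz-6 ADL as
#' "median (IQR)") with the declared between-group test. Patients missing on
#' a variable are excluded from that variable's test when the missing
#' fraction is below the configured threshold (the dementia "unknown" level
#' is pooled with missing for testing but displayed separately).
#'
#' @param records scored patient table.
#' @param variables variables to tabulate; default the standard candidate
#'   set.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame of class \code{tp_baseline}: \code{variable},
#'   \code{level}, \code{overall}, \code{non_textbook}, \code{textbook},
#'   \code{test}, \code{p_value} (test and p on the variable's first row
#'   only).
#' @export
baseline_comparison <- function(records, variables = names(casemix_tests()),
                                config = analysis_config()) {
  assert_config(config)
  if (is.null(records$textbook)) {
    stop_tp("records are not scored; run score_textbook() first")
  }
  present <- variables[variables %in% names(records)]
  absent <- setdiff(variables, present)
  if (length(absent)) {
    warning("variable(s) absent from records, omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  grp <- records$textbook
  dp <- config$round_percent
  n_all <- nrow(records); n_tp <- sum(grp); n_non <- sum(!grp)
  cell <- function(k, n) paste0(k, " (", fmt_pct(100 * k / max(n, 1), dp), "%)")
  rows <- lapply(present, function(v) {
    raw <- records[[v]]
    test <- casemix_tests()[[v]]
    xt <- code_model_var(raw, v)             # test coding (pools unknown)
    keep <- !is.na(xt)
    p <- tryCatch({
      if (test == "t_test") {
        stats::t.test(as.numeric(xt[keep]) ~ grp[keep], var.equal = TRUE)$p.value
      } else if (test == "mann_whitney") {
        stats::wilcox.test(as.numeric(xt[keep]) ~ grp[keep],
                           exact = FALSE)$p.value
      } else {
        suppressWarnings(stats::chisq.test(table(droplevels(xt[keep]),
                                                 grp[keep]),
                                           correct = FALSE)$p.value)
      }
    }, error = function(e) NA_real_)
    if (test == "t_test") {
      x <- as.numeric(raw)
      s <- function(g) sprintf("%.1f (%.1f)", mean(x[g], na.rm = TRUE),
                               stats::sd(x[g], na.rm = TRUE))
      lev_rows <- data.frame(variable = v, level = "mean (SD)",
                             overall = s(rep(TRUE, n_all)),
                             non_textbook = s(!grp), textbook = s(grp),
                             stringsAsFactors = FALSE)
    } else if (test == "mann_whitney") {
      x <- as.numeric(raw)
      s <- function(g) {
        q <- stats::quantile(x[g], c(0.25, 0.5, 0.75), na.rm = TRUE, type = 2)
        sprintf("%g (%g-%g)", q[2], q[1], q[3])
      }
      lev_rows <- data.frame(variable = v, level = "median (IQR)",
                             overall = s(rep(TRUE, n_all)),
                             non_textbook = s(!grp), textbook = s(grp),
                             stringsAsFactors = FALSE)
    } else {
      f <- factor(as.character(raw),
                  levels = union(levels(factor(raw)), unique(as.character(raw))))
      lv <- levels(f)
      lev_rows <- do.call(rbind, lapply(lv, function(l) {
        sel <- !is.na(f) & f == l
        data.frame(variable = v, level = l,
                   overall = cell(sum(sel), n_all),
                   non_textbook = cell(sum(sel & !grp), n_non),
                   textbook = cell(sum(sel & grp), n_tp),
                   stringsAsFactors = FALSE)
      }))
      n_miss <- sum(is.na(f))
      if (n_miss > 0) {
        lev_rows <- rbind(lev_rows, data.frame(
          variable = v, level = "missing",
          overall = cell(n_miss, n_all),
          non_textbook = as.character(sum(is.na(f) & !grp)),
          textbook = as.character(sum(is.na(f) & grp)),
          stringsAsFactors = FALSE))
      }
    }
    lev_rows$test <- c(test, rep("", nrow(lev_rows) - 1L))
    lev_rows$p_value <- c(p, rep(NA_real_, nrow(lev_rows) - 1L))
    lev_rows
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tp_baseline", class(out))
  out
}

#' Construct a 2x2 exposure-outcome table
#'
#' @param a exposed with event; @param b exposed without event;
#' @param c unexposed with event; @param d unexposed without event.
#' @return object of class \code{tp_twobytwo}.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop_tp("2x2 counts must be non-negative")
  structure(list(a = a, b = b, c = c, d = d,
                 event_rate_exposed = a / (a + b),
                 event_rate_unexposed = c / (c + d)),
            class = "tp_twobytwo")
}

#' Cross-product odds ratio with Wald interval
#'
#' OR = (a*d)/(b*c); 95% CI = exp(ln OR +/- z*sqrt(1/a + 1/b + 1/c + 1/d)).
#' With a zero cell the OR is returned where defined and the CI is flagged
#' unavailable, unless \code{config$haldane} enables the Haldane-Anscombe
#' 0.5 correction.
#'
#' @param table a \code{\link{two_by_two}}.
#' @param config an \code{\link{analysis_config}} (supplies \code{z_value}
#'   and the zero-cell policy).
#' @return list: \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{ci_available}.
#' @export
two_by_two_or <- function(table, config = analysis_config()) {
  assert_config(config)
  stopifnot(inherits(table, "tp_twobytwo"))
  cts <- c(table$a, table$b, table$c, table$d)
  if (any(cts == 0) && config$haldane) cts <- cts + 0.5
  a <- cts[1]; b <- cts[2]; c <- cts[3]; d <- cts[4]
  or <- if (b * c > 0) (a * d) / (b * c) else NA_real_
  if (any(cts == 0)) {
    return(list(or = or, ci_low = NA_real_, ci_high = NA_real_,
                ci_available = FALSE))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- config$z_value
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       ci_available = TRUE)
}

#' Flag a prolonged post-operative stay
#'
#' Prolonged length of stay is a post-operative stay of at least the
#' configured cutoff (default 6 days, inclusive). Missing whenever the
#' derived post-operative stay is missing, including stays removed by the
#' 1-year data-entry cap.
#'
#' @param records cleaned patient table (needs \code{postop_stay_days}).
#' @param config an \code{\link{analysis_config}}.
#' @return logical vector (NA = missing).
#' @export
prolonged_stay_flag <- function(records, config = analysis_config()) {
  assert_config(config)
  if (is.null(records$postop_stay_days)) {
    stop_tp("records carry no `postop_stay_days`; run clean_records() first")
  }
  records$postop_stay_days >= config$prolonged_los_cutoff_days
}

outcome_candidates <- function() {
  c("age_years", "sex", "asa_class", "dementia", "katz6_adl",
    "living_situation")
}

outcome_forced <- function() c("textbook", "treatment", "hospital_id")

#' Outcome-association analysis
#'
#' Patient-level association between textbook-process care and an in-hospital
#' outcome. Patients with a missing outcome are excluded and counted. Every
#' case-mix candidate, plus textbook process, treatment type and hospital, is
#' fitted univariably; patient characteristics with univariable p below
#' \code{screening_alpha} enter the multivariable model, in which textbook
#' process, treatment type and hospital are always kept.
#'
#' @param records scored, cleaned patient table.
#' @param outcome \code{"complication_any"} or \code{"prolonged_stay"}.
#' @param config an \code{\link{analysis_config}}.
#' @return list of class \code{tp_outcome_report}: \code{outcome},
#'   \code{univariable} (named list of \code{tp_regression}),
#'   \code{screening} (data.frame variable/p_value/selected),
#'   \code{multivariable} (\code{tp_regression}),
#'   \code{n_missing_outcome}.
#' @export
analyze_outcome <- function(records,
                            outcome = c("complication_any", "prolonged_stay"),
                            config = analysis_config()) {
  assert_config(config)
  outcome <- match.arg(outcome)
  if (is.null(records$textbook)) {
    stop_tp("records are not scored; run score_textbook() first")
  }
  if (outcome == "prolonged_stay") {
    records$prolonged_stay <- prolonged_stay_flag(records, config)
  }
  fitted_terms <- c("textbook", outcome_candidates(), "treatment",
                    "hospital_id")
  uni <- lapply(fitted_terms, function(v)
    fit_logistic(records, outcome, v, config))
  names(uni) <- fitted_terms
  uni_p <- vapply(fitted_terms, function(v) {
    p <- uni[[v]]$terms$p_value
    if (length(p)) min(p) else NA_real_       # multi-level: most extreme level
  }, numeric(1))
  screening <- data.frame(
    variable = outcome_candidates(),
    p_value = uni_p[outcome_candidates()],
    selected = !is.na(uni_p[outcome_candidates()]) &
      uni_p[outcome_candidates()] < config$screening_alpha,
    stringsAsFactors = FALSE)
  multi_terms <- c("textbook", screening$variable[screening$selected],
                   "treatment", "hospital_id")
  multi <- fit_logistic(records, outcome, multi_terms, config)
  structure(list(outcome = outcome,
                 univariable = uni,
                 univariable_p = uni_p,
                 screening = screening,
                 multivariable = multi,
                 n_missing_outcome = multi$n_missing_outcome),
            class = "tp_outcome_report")
}

#' @export
print.tp_outcome_report <- function(x, ...) {
  cat("Outcome analysis:", x$outcome, "\n")
  cat("Screened in (p <", "0.10):",
      paste(x$screening$variable[x$screening$selected], collapse = ", "),
      "\n\nMultivariable model:\n")
  print(x$multivariable)
  invisible(x)
}

#' In-hospital mortality descriptives and feasibility verdict
#'
#' Death rates overall, per textbook group and per hospital, with patients
#' missing the mortality outcome excluded and counted. A multivariable model
#' is attempted only when the event count reaches \code{epv_minimum} events
#' per planned parameter (forced covariates plus screened patient
#' characteristics); otherwise the verdict is descriptive-only with the
#' computed event deficit.
#'
#' @param records scored patient table.
#' @param config an \code{\link{analysis_config}}.
#' @return list of class \code{tp_mortality}: \code{overall} (deaths, n,
#'   rate_percent), \code{by_group}, \code{by_hospital},
#'   \code{n_missing_outcome}, \code{planned_parameters}, \code{verdict}
#'   (\code{"modelled"} or \code{"descriptive_only"}), \code{event_deficit},
#'   and \code{model} (fitted only when feasible).
#' @export
mortality_summary <- function(records, config = analysis_config()) {
  assert_config(config)
  if (is.null(records$textbook)) {
    stop_tp("records are not scored; run score_textbook() first")
  }
  death <- code_outcome(records$in_hospital_death)
  keep <- !is.na(death)
  n_missing <- sum(!keep)
  sub <- records[keep, , drop = FALSE]
  death <- death[keep]
  dp <- config$round_percent
  rate <- function(k, n) if (n > 0) round_half_up(100 * k / n, dp) else NA_real_
  overall <- data.frame(deaths = sum(death), n = length(death),
                        rate_percent = rate(sum(death), length(death)))
  by_group <- do.call(rbind, lapply(c(FALSE, TRUE), function(g) {
    sel <- sub$textbook == g
    data.frame(group = if (g) "textbook" else "non_textbook",
               deaths = sum(death[sel]), n = sum(sel),
               rate_percent = rate(sum(death[sel]), sum(sel)),
               stringsAsFactors = FALSE)
  }))
  hospitals <- sort(unique(as.character(sub$hospital_id)))
  by_hospital <- do.call(rbind, lapply(hospitals, function(h) {
    sel <- as.character(sub$hospital_id) == h
    data.frame(hospital_id = h, deaths = sum(death[sel]), n = sum(sel),
               rate_percent = rate(sum(death[sel]), sum(sel)),
               stringsAsFactors = FALSE)
  }))
  # feasibility: forced terms + screened candidates at epv_minimum
  sub$death <- as.logical(death)
  scr_vars <- tryCatch({
    grp_frame <- sub
    grp_frame$textbook <- sub$death        # group by vital status
    tests <- screen_casemix(grp_frame, outcome_candidates(), config)
    tests$variable[tests$selected]
  }, error = function(e) outcome_candidates())
  n_hosp <- length(hospitals)
  planned <- 1L + 1L + max(n_hosp - 1L, 0L) + length(scr_vars)
  events <- min(sum(death), sum(death == 0))
  required <- config$epv_minimum * planned
  feasible <- events >= required
  model <- NULL
  if (feasible) {
    model <- tryCatch(
      fit_logistic(sub, "death",
                   c("textbook", "treatment", "hospital_id", scr_vars),
                   config),
      error = function(e) NULL)
    if (is.null(model)) feasible <- FALSE
  }
  structure(list(overall = overall, by_group = by_group,
                 by_hospital = by_hospital,
                 n_missing_outcome = n_missing,
                 planned_parameters = planned,
                 verdict = if (feasible) "modelled" else "descriptive_only",
                 event_deficit = max(required - events, 0),
                 model = model),
            class = "tp_mortality")
}

#' @export
print.tp_mortality <- function(x, ...) {
  cat("In-hospital mortality:", x$overall$deaths, "/", x$overall$n,
      paste0("(", x$overall$rate_percent, "%)"), "\n")
  print(x$by_group, row.names = FALSE)
  cat("Verdict:", x$verdict,
      if (x$verdict == "descriptive_only")
        paste0("(", x$event_deficit, " events short of ",
               x$planned_parameters, " planned parameters at EPV ",
               "threshold)") else "", "\n")
  invisible(x)
}
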
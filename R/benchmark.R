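#' Univariable case-mix screening
#'
#' Compares each case-mix candidate between the textbook and non-textbook
#' groups with its declared test: pooled-variance independent-samples t-test
#' for normally distributed continuous variables (age), Mann-Whitney U for
#' non-normal continuous variables (Katz-6 ADL), Pearson chi-square without
#' continuity correction for categoricals. Patients missing on a variable are
#' excluded from that variable's test when the missing fraction is below the
#' configured threshold, else missing is kept as a level (categoricals).
#' Variables with p below \code{screening_alpha} are selected for the
#' adjustment model.
#'
#' @param records scored patient table (needs \code{textbook}).
#' @param candidates case-mix variable names to screen; defaults to the
#'   standard candidate set (see \code{\link{model_variables}}).
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame: \code{variable}, \code{test}, \code{p_value},
#'   \code{selected}.
#' @export
screen_casemix <- function(records, candidates = names(casemix_tests()),
                           config = analysis_config()) {
  assert_config(config)
  tests <- casemix_tests()
  unknown <- setdiff(candidates, names(tests))
  if (length(unknown)) {
    stop_tp("no screening test declared for: ", paste(unknown, collapse = ", "))
  }
  grp <- records$textbook
  out <- lapply(candidates, function(v) {
    x <- code_model_var(records[[v]], v)
    test <- tests[[v]]
    frac <- na_frac(x)
    if (is.factor(x) && frac >= config$missing_category_threshold) {
      lv <- c(levels(x), "missing")
      x <- factor(ifelse(is.na(as.character(x)), "missing",
                         as.character(x)), levels = lv)
    }
    keep <- !is.na(x)
    xs <- x[keep]; gs <- grp[keep]
    p <- tryCatch({
      if (test == "t_test") {
        stats::t.test(as.numeric(xs) ~ gs, var.equal = TRUE)$p.value
      } else if (test == "mann_whitney") {
        stats::wilcox.test(as.numeric(xs) ~ gs, exact = FALSE,
                           correct = TRUE)$p.value
      } else {
        if (is.factor(xs)) xs <- droplevels(xs)
        suppressWarnings(stats::chisq.test(table(xs, gs),
                                           correct = FALSE)$p.value)
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) {
      warning("screening test undefined for '", v,
              "' (constant within groups?); not selected", call. = FALSE)
    }
    data.frame(variable = v, test = test, p_value = p,
               selected = !is.na(p) & p < config$screening_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected textbook-process counts per hospital
#'
#' Indirect standardization: each hospital's expected count E is the sum of
#' its patients' predicted probabilities of textbook-process compliance under
#' the case-mix model (equivalently n times the mean predicted probability).
#' By default the prediction set is the model's fitting set (complete cases);
#' with \code{config$expected_prediction = "all_imputed"} every scored
#' patient is predicted, missing covariates imputed by mode/median.
#'
#' @param model a \code{tp_regression} from \code{\link{fit_logistic}} with
#'   \code{textbook} as outcome.
#' @param records the scored patient table the model was fitted on.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame: \code{hospital_id}, \code{n_pred} (prediction-set
#'   size), \code{expected}.
#' @export
expected_counts <- function(model, records, config = analysis_config()) {
  assert_config(config)
  stopifnot(inherits(model, "tp_regression"))
  if (config$expected_prediction == "complete_cases") {
    probs <- fitted_probs(model)
    hosp <- as.character(model$hospital_id)
  } else {
    terms <- unique(model$terms$term)
    df <- data.frame(row.names = seq_len(nrow(records)))
    for (v in terms) {
      x <- code_model_var(records[[v]], v, hospitals = records$hospital_id)
      if (anyNA(x)) {
        fill <- impute_value(x)
        if (is.factor(x)) x[is.na(x)] <- fill else x[is.na(x)] <- fill
      }
      df[[v]] <- x
    }
    probs <- stats::predict(model$fit, newdata = df, type = "response")
    hosp <- as.character(records$hospital_id)
  }
  agg <- stats::aggregate(probs, by = list(hospital_id = hosp), FUN = sum)
  cnt <- as.data.frame(table(hospital_id = hosp), stringsAsFactors = FALSE)
  out <- merge(cnt, agg, by = "hospital_id")
  names(out) <- c("hospital_id", "n_pred", "expected")
  out[order(out$hospital_id), , drop = FALSE]
}

#' Observed/expected ratio
#'
#' @param observed observed count of textbook-process patients.
#' @param expected expected count from \code{\link{expected_counts}}; must be
#'   positive.
#' @return the unrounded ratio O/E (reporting rounds to the configured
#'   places).
#' @export
compute_oe_ratio <- function(observed, expected) {
  if (any(expected <= 0)) stop_tp("expected count must be positive")
  observed / expected
}

#' Confidence interval for O = E
#'
#' The indirect-standardization control limits for the null hypothesis that
#' the observed count equals the expected count:
#' lower = (sqrt(E) - z/2)^2 / E, upper = (sqrt(E) + z/2)^2 / E. A hospital
#' whose O/E ratio falls outside this interval performed significantly worse
#' or better than expected from its case-mix.
#'
#' @param expected expected count E (> 0).
#' @param z standard-normal quantile (1.96 for 95% limits).
#' @return data.frame with \code{ci_low}, \code{ci_high} (unrounded).
#' @export
oe_confidence_interval <- function(expected, z = 1.96) {
  if (any(expected <= 0)) stop_tp("expected count must be positive")
  data.frame(ci_low = (sqrt(expected) - z / 2)^2 / expected,
             ci_high = (sqrt(expected) + z / 2)^2 / expected)
}

#' Classify a hospital against its O = E interval
#'
#' @param oe_ratio observed/expected ratio.
#' @param ci_low,ci_high interval bounds from
#'   \code{\link{oe_confidence_interval}}.
#' @return \code{"better"} if above the upper bound, \code{"worse"} if below
#'   the lower bound, else \code{"as_expected"} (boundaries inclusive to
#'   as_expected).
#' @export
classify_hospital <- function(oe_ratio, ci_low, ci_high) {
  ifelse(oe_ratio > ci_high, "better",
         ifelse(oe_ratio < ci_low, "worse", "as_expected"))
}

#' Case-mix adjusted hospital benchmarking
#'
#' The full profiling chain: screen the case-mix candidates against textbook
#' process, fit the expected-compliance logistic model on the selected
#' variables (intercept-only if none is selected), compute each hospital's
#' expected count, O/E ratio and O = E interval, and classify the hospital.
#' The observed rate and n are over all scored patients; the observed count
#' entering the O/E ratio is taken on the same patient set the expected
#' count is summed over (the prediction set), keeping O and E comparable.
#'
#' @param records scored patient table (see \code{\link{score_textbook}}).
#' @param candidates case-mix candidates for screening.
#' @param config an \code{\link{analysis_config}}.
#' @return list of class \code{tp_benchmark}: \code{table} (one row per
#'   hospital: n, observed, observed_rate, n_pred, expected, oe_ratio,
#'   ci_low, ci_high, classification; ratios unrounded), \code{screening},
#'   \code{model}.
#' @export
benchmark_hospitals <- function(records, candidates = names(casemix_tests()),
                                config = analysis_config()) {
  assert_config(config)
  if (is.null(records$textbook)) {
    stop_tp("records are not scored; run score_textbook() first")
  }
  screening <- screen_casemix(records, candidates, config)
  selected <- screening$variable[screening$selected]
  model <- fit_logistic(records, "textbook", selected, config)
  exp_tab <- expected_counts(model, records, config)
  # O is counted on the same patient set E is summed over, so that O and E
  # are comparable (over the whole cohort they then agree exactly, by the
  # logistic score equation, when predicting on the fitting set)
  if (config$expected_prediction == "complete_cases") {
    obs_ids <- model$patient_id
    obs_hosp <- as.character(model$hospital_id)
    obs_tp <- records$textbook[match(obs_ids, records$patient_id)]
  } else {
    obs_hosp <- as.character(records$hospital_id)
    obs_tp <- records$textbook
  }
  obs <- stats::aggregate(as.numeric(obs_tp),
                          by = list(hospital_id = obs_hosp), FUN = sum)
  names(obs) <- c("hospital_id", "observed")
  cnt <- as.data.frame(table(hospital_id = as.character(records$hospital_id)),
                       stringsAsFactors = FALSE)
  names(cnt) <- c("hospital_id", "n")
  rate <- stats::aggregate(as.numeric(records$textbook),
                           by = list(hospital_id = as.character(records$hospital_id)),
                           FUN = mean)
  names(rate) <- c("hospital_id", "observed_rate")
  rate$observed_rate <- 100 * rate$observed_rate
  tab <- merge(merge(merge(cnt, rate, by = "hospital_id"), obs,
                     by = "hospital_id", all.x = TRUE),
               exp_tab, by = "hospital_id", all.x = TRUE)
  if (anyNA(tab$expected)) {
    warning("hospital(s) with empty prediction set omitted: ",
            paste(tab$hospital_id[is.na(tab$expected)], collapse = ", "),
            call. = FALSE)
    tab <- tab[!is.na(tab$expected), , drop = FALSE]
  }
  tab$oe_ratio <- compute_oe_ratio(tab$observed, tab$expected)
  ci <- oe_confidence_interval(tab$expected, config$z_value)
  tab$ci_low <- ci$ci_low
  tab$ci_high <- ci$ci_high
  tab$classification <- classify_hospital(tab$oe_ratio, tab$ci_low,
                                          tab$ci_high)
  tab <- tab[order(tab$hospital_id),
             c("hospital_id", "n", "observed", "observed_rate", "n_pred",
               "expected", "oe_ratio", "ci_low", "ci_high",
               "classification")]
  rownames(tab) <- NULL
  structure(list(table = tab, screening = screening, model = model),
            class = "tp_benchmark")
}

#' @export
print.tp_benchmark <- function(x, ...) {
  cat("Case-mix adjusted hospital benchmark (textbook process)\n")
  cat("Adjusted for:",
      if (nrow(x$model$terms)) paste(unique(x$model$terms$term),
                                     collapse = ", ") else "(intercept only)",
      "\n")
  tab <- x$table
  tab$observed_rate <- round_half_up(tab$observed_rate, 1)
  tab$expected <- round_half_up(tab$expected, 2)
  tab$oe_ratio <- round_half_up(tab$oe_ratio, 2)
  tab$ci_low <- round_half_up(tab$ci_low, 2)
  tab$ci_high <- round_half_up(tab$ci_high, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
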
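#' @name model_variables
#' @title Model variable metadata
#'
#' @description
#' The case-mix candidates, their screening test and their model coding. Age
#' and Katz-6 ADL enter models as continuous per-unit terms; ASA as binary
#' (1-2 vs 3-4); dementia as binary yes/no with the "unknown" level pooled
#' with missing; reference levels are female sex, ASA 1-2, no dementia,
#' independent living, osteosynthesis, and (for hospital contrasts) the
#' fourth hospital in sorted order.
NULL

casemix_tests <- function() {
  c(age_years = "t_test",
    sex = "chi_square",
    asa_class = "chi_square",
    dementia = "chi_square",
    katz6_adl = "mann_whitney",
    living_situation = "chi_square",
    fracture_type = "chi_square",
    treatment = "chi_square")
}

reference_levels <- function() {
  c(sex = "female", asa_class = "asa12", dementia = "no",
    living_situation = "independent", treatment = "osteosynthesis")
}

hospital_reference <- function(hospitals) {
  hospitals <- sort(unique(as.character(hospitals)))
  if (length(hospitals) >= 4) hospitals[4] else hospitals[1]
}

# Coerce one model variable: pool dementia "unknown" with missing, relevel
# factors to the documented references, keep numerics numeric.
code_model_var <- function(x, var, hospitals = NULL) {
  if (var == "dementia") {
    x <- as.character(x)
    x[x == "unknown"] <- NA_character_
    return(stats::relevel(factor(x, levels = c("no", "yes")), ref = "no"))
  }
  if (var == "hospital_id") {
    return(stats::relevel(factor(as.character(x)),
                          ref = hospital_reference(hospitals %||% x)))
  }
  if (var == "textbook") return(as.numeric(x))
  refs <- reference_levels()
  if (var %in% names(refs)) {
    f <- factor(as.character(x))
    if (!refs[[var]] %in% levels(f)) return(f)
    return(stats::relevel(f, ref = refs[[var]]))
  }
  if (is.factor(x)) return(factor(as.character(x)))
  as.numeric(x)
}

# Outcome as 0/1: logicals as-is; yes/no factors with "yes" the event.
code_outcome <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) return(x)
  as.numeric(as.character(x) == "yes")
}

# Build the model frame: code variables, apply the per-variable missing rule
# (< threshold: drop the rows; otherwise keep "missing" as an explicit level
# for categoricals), then listwise-delete whatever missingness remains.
prepare_model_frame <- function(records, outcome, terms,
                                config = analysis_config()) {
  y <- code_outcome(records[[outcome]])
  keep <- !is.na(y)
  df <- data.frame(.y = y[keep])
  sub <- records[keep, , drop = FALSE]
  for (v in terms) {
    x <- code_model_var(sub[[v]], v, hospitals = records$hospital_id)
    frac <- na_frac(x)
    if (frac >= config$missing_category_threshold && is.factor(x)) {
      lv <- c(levels(x), "missing")
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      x <- factor(x, levels = lv)
    }
    df[[v]] <- x
  }
  cc <- stats::complete.cases(df)
  list(frame = df[cc, , drop = FALSE],
       hospital_id = sub$hospital_id[cc],
       patient_id = sub$patient_id[cc],
       n_missing_outcome = sum(!keep),
       n_dropped_covariates = sum(!cc))
}

#' Fit a maximum-likelihood logistic regression
#'
#' Thin, audited wrapper around \code{stats::glm(family = binomial)} with the
#' pipeline's coding conventions: documented reference levels, the
#' per-variable missing rule before listwise deletion, Wald confidence
#' intervals at the configured quantile, an explicit refusal when there are
#' fewer outcome events (or non-events) than parameters, and an explicit
#' error naming the offending term under perfect separation.
#'
#' @param records patient table (scored, if \code{textbook} is a term).
#' @param outcome outcome column name; logical, 0/1, or a yes/no factor with
#'   \code{"yes"} the event.
#' @param terms character vector of covariate column names; empty for an
#'   intercept-only model.
#' @param config an \code{\link{analysis_config}}.
#' @return object of class \code{tp_regression}: a list with \code{outcome},
#'   \code{terms} (data.frame: term, level, reference, estimate, se, or,
#'   ci_low, ci_high, p_value), \code{intercept}, \code{n_used},
#'   \code{events}, \code{converged}, and the underlying \code{fit}.
#' @export
fit_logistic <- function(records, outcome, terms = character(),
                         config = analysis_config()) {
  assert_config(config)
  prep <- prepare_model_frame(records, outcome, terms, config)
  df <- prep$frame
  # drop terms constant after preparation (no contrast possible)
  terms_used <- terms[vapply(terms, function(v) {
    x <- df[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else stats::var(x) > 0
  }, logical(1))]
  dropped_const <- setdiff(terms, terms_used)
  if (length(dropped_const)) {
    warning("dropping constant term(s): ",
            paste(dropped_const, collapse = ", "), call. = FALSE)
  }
  for (v in terms_used) if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  fml <- stats::reformulate(if (length(terms_used)) terms_used else "1",
                            response = ".y")
  events <- sum(df$.y)
  n_par <- 1L + sum(vapply(terms_used, function(v)
    if (is.factor(df[[v]])) nlevels(df[[v]]) - 1L else 1L, integer(1)))
  if (min(events, nrow(df) - events) < n_par) {
    stop_tp("events-per-variable failure: ", min(events, nrow(df) - events),
            " events for ", n_par, " parameters")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  # separation: a drifting estimate with an exploding Wald SE (glm itself
  # may neither warn nor flag non-convergence)
  drift <- abs(sm[-1, "Estimate"]) > 10 & sm[-1, "Std. Error"] > 25
  if ((sep_warn && any(abs(cf[-1]) > 10)) || any(drift)) {
    bad <- if (any(drift)) rownames(sm)[-1][which(drift)[1]] else
      names(cf[-1])[which.max(abs(cf[-1]))]
    stop_tp("perfect separation: model did not converge; separating term: ",
            bad)
  }
  z <- config$z_value
  tidy <- do.call(rbind, lapply(terms_used, function(v) {
    x <- df[[v]]
    if (is.factor(x)) {
      lv <- levels(x)[-1]
      rows <- paste0(v, lv)
      data.frame(term = v, level = lv, reference = levels(x)[1],
                 row = rows, stringsAsFactors = FALSE)
    } else {
      data.frame(term = v, level = "", reference = "", row = v,
                 stringsAsFactors = FALSE)
    }
  }))
  if (is.null(tidy)) {
    tidy <- data.frame(term = character(), level = character(),
                       reference = character(), row = character(),
                       stringsAsFactors = FALSE)
  }
  est <- sm[tidy$row, "Estimate"]
  se <- sm[tidy$row, "Std. Error"]
  terms_df <- data.frame(
    term = tidy$term, level = tidy$level, reference = tidy$reference,
    estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - z * unname(se)),
    ci_high = exp(unname(est) + z * unname(se)),
    p_value = unname(sm[tidy$row, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  structure(list(
    outcome = outcome,
    terms = terms_df,
    intercept = unname(cf[1]),
    n_used = nrow(df),
    events = events,
    n_missing_outcome = prep$n_missing_outcome,
    n_dropped_covariates = prep$n_dropped_covariates,
    converged = fit$converged && !sep_warn,
    hospital_id = prep$hospital_id,
    patient_id = prep$patient_id,
    fit = fit
  ), class = "tp_regression")
}

#' @export
print.tp_regression <- function(x, ...) {
  cat("Logistic regression:", x$outcome, "~",
      if (nrow(x$terms)) paste(unique(x$terms$term), collapse = " + ")
      else "1", "\n")
  cat("n =", x$n_used, "; events =", x$events,
      "; converged:", x$converged, "\n")
  if (nrow(x$terms)) {
    tab <- x$terms
    tab$or <- round_half_up(tab$or, 2)
    tab$ci_low <- round_half_up(tab$ci_low, 2)
    tab$ci_high <- round_half_up(tab$ci_high, 2)
    tab$p_value <- signif(tab$p_value, 2)
    print(tab[c("term", "level", "reference", "or", "ci_low", "ci_high",
                "p_value")], row.names = FALSE)
  }
  invisible(x)
}

# predicted probabilities on the fitting set
fitted_probs <- function(model) {
  stopifnot(inherits(model, "tp_regression"))
  unname(stats::fitted(model$fit))
}
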
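# Fixtures built in code; no stored data files.

ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# A minimal hand-written patient table in the registry dialect.
tiny_cohort <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3"),
    hospital_id = c("H1", "H1", "H2"),
    age_years = c(82L, 90L, 75L),
    sex = factor(c("female", "male", "female"), c("female", "male")),
    asa_class = factor(c("asa12", "asa34", "asa34"), c("asa12", "asa34")),
    dementia = factor(c("no", "yes", "no"), c("no", "yes", "unknown")),
    katz6_adl = c(1L, 4L, 0L),
    living_situation = factor(c("independent", "institutionalized",
                                "independent"),
                              c("independent", "institutionalized")),
    fracture_type = factor(c("fn_displaced", "a2", "a1"),
                           c("fn_nondisplaced", "fn_displaced", "a1", "a2",
                             "a3", "subtrochanteric")),
    pathologic_fracture = c(FALSE, FALSE, FALSE),
    periprosthetic_fracture = c(FALSE, FALSE, FALSE),
    treatment = factor(c("prosthesis", "osteosynthesis", "osteosynthesis"),
                       c("osteosynthesis", "prosthesis")),
    ed_arrival = ts(c("2018-03-01T10:00:00", "2018-05-10T22:30:00",
                      "2018-07-01T08:00:00")),
    surgery_start = ts(c("2018-03-02T09:00:00", "2018-05-12T01:30:00",
                         "2018-07-01T15:00:00")),
    discharge = ts(c("2018-03-08T09:00:00", "2018-05-20T12:00:00",
                     "2018-07-05T10:00:00")),
    malnutrition_assessed = factor(c("met", "met", "not_met"),
                                   c("met", "not_met")),
    orthogeriatric_management = factor(c("met", "met", "met"),
                                       c("met", "not_met")),
    certified_surgeon = factor(c("met", "not_met", "met"),
                               c("met", "not_met")),
    complication_any = factor(c("no", "yes", "no"), c("yes", "no")),
    complication_types = c("", "delirium", ""),
    in_hospital_death = factor(c("no", "no", "no"), c("yes", "no")),
    stringsAsFactors = FALSE
  )
}

# Deterministic scored cohort from the generator.
scored_cohort <- function(seed = 42, config = analysis_config(), ...) {
  sim <- generate_registry(synthetic_config(seed = seed, ...))
  cleaned <- clean_records(sim$records, config)
  elig <- select_eligible(cleaned, config)
  score_textbook(elig$records, config)
}

# Independent brute-force ML logistic oracle: coarse grid start, then
# Nelder-Mead polish of the exact negative log-likelihood.
brute_force_logistic <- function(X, y) {
  nll <- function(beta) {
    eta <- as.vector(X %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  p <- ncol(X)
  starts <- as.matrix(expand.grid(rep(list(c(-2, 0, 2)), p)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  stats::optim(best$par, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}
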
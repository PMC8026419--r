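#' Synthetic registry configuration
#'
#' Parameters of the synthetic hip-fracture registry generator. Defaults are
#' calibrated to a five-hospital elderly cohort: hospital sizes
#' 307/205/281/327/251 (1371 patients), age ~ Normal(84, 7.1) truncated to
#' 70-105, 69% female, 63% ASA 3-4, 23% dementia, Katz-6 ADL integers with
#' median 1 and IQR 0-4, 30% institutionalized, 45% prosthesis. Per-hospital
#' indicator compliance spans a wide low-to-high range so that observed
#' textbook-process rates bracket roughly 38-76%; an ASA 3-4 log-odds effect
#' of -0.61 on the surgery-within-24h indicator reproduces a ~62% vs ~52%
#' textbook-process split by ASA group. Outcome models use a
#' textbook-process log-odds of ln(0.66) for complications (with age, ASA,
#' Katz and hospital effects), ln(1.01) for prolonged stay, and a 2.8%
#' baseline in-hospital mortality.
#'
#' @param hospital_sizes named integer vector of patients per hospital.
#' @param casemix list of case-mix marginals (see defaults).
#' @param indicators matrix (hospitals x 4 indicators) of marginal compliance
#'   probabilities.
#' @param casemix_effects named list: per indicator, named log-odds effects
#'   of covariates (\code{asa34}, \code{age_c} = age - 84, \code{katz}) on
#'   compliance; per-hospital intercepts are solved so the configured
#'   marginal compliance is preserved.
#' @param tts_lognormal \code{c(meanlog, sdlog)} of the hours-to-surgery
#'   distribution, sampled consistently with each patient's drawn
#'   within-24h status.
#' @param outcomes list of coefficient vectors for the complication,
#'   prolonged-stay and mortality models (log-odds; age centered at 84).
#' @param missingness named per-field missing-completely-at-random rates.
#' @param mar_asa if TRUE, ASA missingness is twice as likely for ASA 3-4
#'   patients (marginal rate preserved).
#' @param planted named counts of eligibility violations to plant
#'   (\code{age}, \code{window}, \code{pathologic}, \code{periprosthetic},
#'   \code{mandatory}); applied to the first rows of the cohort, one reason
#'   each, so exclusion tallies are exact.
#' @param seed integer RNG seed; must be supplied before generation.
#' @return object of class \code{tp_syncfg}.
#' @export
synthetic_config <- function(
    hospital_sizes = c(H1 = 307, H2 = 205, H3 = 281, H4 = 327, H5 = 251),
    casemix = list(
      age_mean = 84, age_sd = 7.1, age_range = c(70, 105),
      female = 0.69, asa34 = 0.63,
      dementia_yes = 0.23, dementia_unknown = 0.024,
      katz_probs = c(0.35, 0.17, 0.12, 0.10, 0.10, 0.08, 0.08),
      institutionalized = 0.30,
      fracture_probs = c(fn_nondisplaced = 0.126, fn_displaced = 0.421,
                         a1 = 0.146, a2 = 0.207, a3 = 0.077,
                         subtrochanteric = 0.023),
      prosthesis = 0.45),
    indicators = rbind(
      H1 = c(malnutrition = 0.94, surgery_within_24h = 0.520,
             orthogeriatric = 0.82, certified_surgeon = 0.890),
      H2 = c(malnutrition = 0.97, surgery_within_24h = 0.955,
             orthogeriatric = 0.97, certified_surgeon = 0.950),
      H3 = c(malnutrition = 0.95, surgery_within_24h = 0.780,
             orthogeriatric = 0.93, certified_surgeon = 0.955),
      H4 = c(malnutrition = 0.94, surgery_within_24h = 0.640,
             orthogeriatric = 0.90, certified_surgeon = 0.940),
      H5 = c(malnutrition = 0.97, surgery_within_24h = 0.700,
             orthogeriatric = 0.96, certified_surgeon = 0.950)),
    casemix_effects = list(surgery_within_24h = c(asa34 = -0.61)),
    tts_lognormal = c(meanlog = log(18), sdlog = 0.55),
    outcomes = list(
      complication = list(intercept = -0.38, textbook = log(0.66),
                          age_c = log(1.06), asa34 = log(1.37),
                          katz = log(1.02),
                          hospital = c(H1 = log(0.99), H2 = log(0.52),
                                       H3 = log(1.39), H4 = 0,
                                       H5 = log(1.43))),
      prolonged = list(intercept = 0.24, textbook = log(1.01),
                       age_c = log(1.05), asa34 = log(1.48),
                       katz = log(1.10), dementia = log(0.79),
                       institutionalized = log(0.16),
                       prosthesis = log(0.81),
                       hospital = c(H1 = log(0.82), H2 = log(0.62),
                                    H3 = log(0.62), H4 = 0,
                                    H5 = log(0.98))),
      mortality = list(intercept = -3.41, textbook = -0.71)),
    missingness = c(sex = 0.0015, asa_class = 0.033, dementia = 0.015,
                    katz6_adl = 0.048, living_situation = 0.0036,
                    fracture_type = 0.018, malnutrition_assessed = 0.016,
                    orthogeriatric_management = 0.016,
                    certified_surgeon = 0.016, complication_any = 0.0007,
                    in_hospital_death = 0.0015, discharge = 0.005),
    mar_asa = FALSE,
    planted = c(age = 0, window = 0, pathologic = 0, periprosthetic = 0,
                mandatory = 0),
    seed = NULL) {
  if (is.null(names(hospital_sizes))) {
    names(hospital_sizes) <- paste0("H", seq_along(hospital_sizes))
  }
  if (any(hospital_sizes <= 0)) stop_tp("hospital sizes must be positive")
  fracs <- c(casemix$female, casemix$asa34, casemix$dementia_yes,
             casemix$dementia_unknown, casemix$institutionalized,
             casemix$prosthesis, casemix$katz_probs,
             casemix$fracture_probs, as.vector(indicators), missingness)
  if (any(fracs < 0 | fracs > 1)) {
    stop_tp("all fractions and probabilities must lie in [0, 1]")
  }
  if (any(indicators <= 0 | indicators >= 1)) {
    stop_tp("indicator compliance probabilities must lie strictly in (0, 1)")
  }
  if (!identical(sort(rownames(indicators)), sort(names(hospital_sizes)))) {
    stop_tp("indicator matrix rows must match hospital names")
  }
  structure(list(hospital_sizes = hospital_sizes, casemix = casemix,
                 indicators = indicators, casemix_effects = casemix_effects,
                 tts_lognormal = tts_lognormal, outcomes = outcomes,
                 missingness = missingness, mar_asa = mar_asa,
                 planted = planted, seed = seed),
            class = "tp_syncfg")
}

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Solve the per-hospital indicator intercept a so that
# mean(plogis(a + lp)) equals the configured marginal compliance.
solve_intercept <- function(target, lp) {
  if (all(lp == 0)) return(stats::qlogis(target))
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 interval = c(-15, 15), tol = 1e-10)$root
}

complication_subtypes <- function() {
  c(anaemia = 0.18, delirium = 0.22, pneumonia = 0.12,
    urinary_tract_infection = 0.14, in_hospital_fall = 0.08,
    heart_failure = 0.07, renal_insufficiency = 0.07,
    pulmonary_embolism = 0.03, wound_infection = 0.04,
    pressure_ulcer = 0.05)
}

#' Generate a synthetic hip-fracture registry
#'
#' Draws a fully synthetic five-hospital (by default) registry: case-mix per
#' patient, indicator compliance from per-hospital logistic models (the
#' configured case-mix effects shift the linear predictor and the hospital
#' intercept is solved so the marginal compliance matches the configured
#' probability), time to surgery from a log-normal sampled consistently with
#' the drawn within-24h status, timestamps, in-hospital outcomes from the
#' configured logistic models given the realized textbook-process status,
#' and finally missing-completely-at-random masking. Deterministic for a
#' given seed: one RNG stream, field draw order frozen.
#'
#' @param config a \code{\link{synthetic_config}} with \code{seed} set.
#' @return list with \code{records} (a typed patient table in the registry
#'   dialect) and \code{truth} (ground-truth sidecar: the generating
#'   parameters plus each patient's latent indicator statuses, true
#'   textbook-process status and outcome draws, before masking).
#' @export
generate_registry <- function(config = synthetic_config(seed = 1)) {
  if (!inherits(config, "tp_syncfg")) {
    stop_tp("`config` must be created by synthetic_config()")
  }
  if (is.null(config$seed)) stop_tp("config$seed must be supplied")
  set.seed(as.integer(config$seed))
  cm <- config$casemix
  sizes <- config$hospital_sizes
  n <- sum(sizes)
  hospital <- rep(names(sizes), times = sizes)

  # --- case-mix (draw order frozen) ---
  lo <- stats::pnorm(cm$age_range[1] - 0.5, cm$age_mean, cm$age_sd)
  hi <- stats::pnorm(cm$age_range[2] + 0.5, cm$age_mean, cm$age_sd)
  age <- as.integer(round(stats::qnorm(stats::runif(n, lo, hi),
                                       cm$age_mean, cm$age_sd)))
  age <- pmin(pmax(age, cm$age_range[1]), cm$age_range[2])
  sex <- ifelse(stats::runif(n) < cm$female, "female", "male")
  asa34 <- stats::runif(n) < cm$asa34
  u_dem <- stats::runif(n)
  dementia <- ifelse(u_dem < cm$dementia_yes, "yes",
                     ifelse(u_dem < cm$dementia_yes + cm$dementia_unknown,
                            "unknown", "no"))
  katz <- sample(0:6, n, replace = TRUE, prob = cm$katz_probs)
  living <- ifelse(stats::runif(n) < cm$institutionalized,
                   "institutionalized", "independent")
  fracture <- sample(names(cm$fracture_probs), n, replace = TRUE,
                     prob = cm$fracture_probs)
  treatment <- ifelse(stats::runif(n) < cm$prosthesis,
                      "prosthesis", "osteosynthesis")

  # --- arrival timestamps: margin so surgery stays inside the window ---
  window <- as.POSIXct(c("2018-01-01 00:00:00", "2018-12-17 00:00:00"),
                       tz = "UTC")
  ed_arrival <- window[1] +
    round(stats::runif(n, 0, as.numeric(difftime(window[2], window[1],
                                                 units = "mins")))) * 60

  # --- indicator compliance ---
  covars <- list(asa34 = as.numeric(asa34), age_c = age - cm$age_mean,
                 katz = katz)
  met <- matrix(NA, n, 4, dimnames = list(NULL, tp_indicators()))
  p_ind <- matrix(NA_real_, n, 4, dimnames = list(NULL, tp_indicators()))
  for (ind in tp_indicators()) {
    eff <- config$casemix_effects[[ind]]
    lp <- rep(0, n)
    for (cv in names(eff)) lp <- lp + eff[[cv]] * covars[[cv]]
    for (h in names(sizes)) {
      sel <- hospital == h
      a <- solve_intercept(config$indicators[h, ind], lp[sel])
      p_ind[sel, ind] <- clip_prob(stats::plogis(a + lp[sel]))
    }
    met[, ind] <- stats::runif(n) < p_ind[, ind]
  }

  # --- time to surgery consistent with the drawn 24h status ---
  ml <- config$tts_lognormal[["meanlog"]]
  sl <- config$tts_lognormal[["sdlog"]]
  f24 <- stats::plnorm(24, ml, sl)
  f336 <- stats::plnorm(336, ml, sl)
  u <- stats::runif(n)
  tts_hours <- ifelse(met[, "surgery_within_24h"],
                      stats::qlnorm(u * f24, ml, sl),
                      stats::qlnorm(f24 + u * (f336 - f24), ml, sl))
  tts_min <- pmax(round(tts_hours * 60), 30)
  tts_min <- ifelse(met[, "surgery_within_24h"],
                    pmin(tts_min, 24 * 60),
                    pmax(pmin(tts_min, 336 * 60 - 1), 24 * 60 + 1))
  surgery_start <- ed_arrival + tts_min * 60
  tp_true <- rowSums(met) == 4L

  # --- outcomes given realized textbook process ---
  oc <- config$outcomes$complication
  lp_c <- oc$intercept + oc$textbook * tp_true + oc$age_c * (age - cm$age_mean) +
    oc$asa34 * as.numeric(asa34) + oc$katz * katz +
    unname(oc$hospital[hospital])
  complication <- stats::runif(n) < clip_prob(stats::plogis(lp_c))

  op <- config$outcomes$prolonged
  lp_p <- op$intercept + op$textbook * tp_true + op$age_c * (age - cm$age_mean) +
    op$asa34 * as.numeric(asa34) + op$katz * katz +
    op$dementia * (dementia == "yes") +
    op$institutionalized * (living == "institutionalized") +
    op$prosthesis * (treatment == "prosthesis") +
    unname(op$hospital[hospital])
  prolonged <- stats::runif(n) < clip_prob(stats::plogis(lp_p))

  # post-operative stay consistent with the prolonged-stay flag
  u2 <- stats::runif(n)
  f6 <- stats::plnorm(6, log(4), 0.6)
  postop_days <- ifelse(prolonged,
                        6 + stats::qexp(u2, rate = 1 / 3),
                        stats::qlnorm(u2 * f6, log(4), 0.6))
  postop_min <- round(postop_days * 24 * 60)
  postop_min <- ifelse(prolonged, pmax(postop_min, 6 * 24 * 60),
                       pmax(pmin(postop_min, 6 * 24 * 60 - 1), 60))
  discharge <- surgery_start + postop_min * 60

  om <- config$outcomes$mortality
  death <- stats::runif(n) <
    clip_prob(stats::plogis(om$intercept + om$textbook * tp_true))

  # complication subtypes conditional on an event
  subtype_p <- complication_subtypes()
  first <- sample(names(subtype_p), n, replace = TRUE, prob = subtype_p)
  second <- sample(names(subtype_p), n, replace = TRUE, prob = subtype_p)
  has_second <- stats::runif(n) < 0.3 & second != first
  types <- ifelse(complication,
                  ifelse(has_second, paste(first, second, sep = ";"), first),
                  "")

  spec <- registry_spec()
  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    hospital_id = hospital,
    age_years = age,
    sex = factor(sex, levels = spec$category$sex),
    asa_class = factor(ifelse(asa34, "asa34", "asa12"),
                       levels = spec$category$asa_class),
    dementia = factor(dementia, levels = spec$category$dementia),
    katz6_adl = as.integer(katz),
    living_situation = factor(living, levels = spec$category$living_situation),
    fracture_type = factor(fracture, levels = spec$category$fracture_type),
    pathologic_fracture = FALSE,
    periprosthetic_fracture = FALSE,
    treatment = factor(treatment, levels = spec$category$treatment),
    ed_arrival = ed_arrival,
    surgery_start = surgery_start,
    discharge = discharge,
    malnutrition_assessed = factor(
      ifelse(met[, "malnutrition"], "met", "not_met"), c("met", "not_met")),
    orthogeriatric_management = factor(
      ifelse(met[, "orthogeriatric"], "met", "not_met"), c("met", "not_met")),
    certified_surgeon = factor(
      ifelse(met[, "certified_surgeon"], "met", "not_met"),
      c("met", "not_met")),
    complication_any = factor(ifelse(complication, "yes", "no"),
                              levels = spec$category$complication_any),
    complication_types = types,
    in_hospital_death = factor(ifelse(death, "yes", "no"),
                               levels = spec$category$in_hospital_death),
    stringsAsFactors = FALSE
  )

  truth <- list(
    seed = config$seed,
    parameters = config[c("hospital_sizes", "casemix", "indicators",
                          "casemix_effects", "outcomes", "missingness")],
    patients = data.frame(
      patient_id = records$patient_id,
      hospital_id = hospital,
      malnutrition_met = met[, "malnutrition"],
      surgery_within_24h_met = met[, "surgery_within_24h"],
      orthogeriatric_met = met[, "orthogeriatric"],
      certified_surgeon_met = met[, "certified_surgeon"],
      tts_hours = tts_min / 60,
      textbook_true = tp_true,
      complication_true = complication,
      prolonged_true = prolonged,
      death_true = death,
      stringsAsFactors = FALSE)
  )

  records <- mask_fields(records, config$missingness, mar_asa = config$mar_asa)
  records <- plant_violations(records, config$planted)
  list(records = records, truth = truth)
}

# MCAR masking core (uses the current RNG stream)
mask_fields <- function(records, rates, mar_asa = FALSE) {
  n <- nrow(records)
  for (field in names(rates)) {
    r <- rates[[field]]
    if (r <= 0) next
    if (field == "asa_class" && mar_asa) {
      w <- ifelse(records$asa_class %in% "asa34", 2, 1)
      p <- r * w / mean(w)
      hit <- stats::runif(n) < p
    } else {
      hit <- stats::runif(n) < r
    }
    if (!any(hit)) next
    if (field == "discharge") {
      records$discharge[hit] <- as.POSIXct(NA)
    } else if (field == "complication_any") {
      records$complication_any[hit] <- NA
      records$complication_types[hit] <- ""
    } else {
      records[[field]][hit] <- NA
    }
  }
  records
}

#' Mask registry fields completely at random
#'
#' Standalone missingness injector: masks each configured field at its rate,
#' independently per patient. Masking an indicator field makes the
#' downstream indicator tri-state missing, which forces the composite to
#' non-textbook.
#'
#' @param records patient table.
#' @param rates named per-field rates in [0, 1].
#' @param seed integer seed (one stream; omit to continue the current one).
#' @return the masked table.
#' @export
inject_missingness <- function(records, rates, seed = NULL) {
  if (any(rates < 0 | rates > 1)) stop_tp("rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(records))
  if (length(bad)) stop_tp("unknown field(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mask_fields(records, rates)
}

# Overwrite the first rows with one eligibility violation each (disjoint
# rows, fixed reason order) so exclusion tallies are exactly the planted
# counts.
plant_violations <- function(records, planted) {
  if (is.null(planted) || sum(planted) == 0) return(records)
  i <- 1L
  take <- function(k) {
    idx <- seq.int(i, length.out = k)
    i <<- i + k
    idx
  }
  if (planted[["age"]] > 0) {
    records$age_years[take(planted[["age"]])] <- 69L
  }
  if (planted[["window"]] > 0) {
    idx <- take(planted[["window"]])
    shift <- 370 * 86400
    records$ed_arrival[idx] <- records$ed_arrival[idx] + shift
    records$surgery_start[idx] <- records$surgery_start[idx] + shift
    records$discharge[idx] <- records$discharge[idx] + shift
  }
  if (planted[["pathologic"]] > 0) {
    records$pathologic_fracture[take(planted[["pathologic"]])] <- TRUE
  }
  if (planted[["periprosthetic"]] > 0) {
    records$periprosthetic_fracture[take(planted[["periprosthetic"]])] <- TRUE
  }
  if (planted[["mandatory"]] > 0) {
    records$ed_arrival[take(planted[["mandatory"]])] <- as.POSIXct(NA)
  }
  if (i - 1L > nrow(records)) stop_tp("more planted violations than records")
  records
}
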
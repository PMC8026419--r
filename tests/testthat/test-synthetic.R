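test_that("generation is deterministic for a fixed seed", {
  a <- generate_registry(synthetic_config(seed = 8))
  b <- generate_registry(synthetic_config(seed = 8))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$patients, b$truth$patients)
  c <- generate_registry(synthetic_config(seed = 9))
  expect_false(identical(a$records, c$records))
})

test_that("default configuration carries the calibrated study conditions", {
  cfg <- synthetic_config(seed = 1)
  expect_equal(sum(cfg$hospital_sizes), 1371)
  expect_equal(cfg$casemix$female, 0.69)
  expect_equal(cfg$outcomes$complication$textbook, log(0.66),
               tolerance = 1e-12)
  expect_equal(cfg$casemix$age_mean, 84)
  expect_error(generate_registry(synthetic_config()), "seed")
})

test_that("infeasible configurations fail validation before any draw", {
  expect_error(synthetic_config(casemix = modifyList(
    synthetic_config(seed = 1)$casemix, list(female = 1.2))), "0, 1")
  ind <- synthetic_config(seed = 1)$indicators
  ind["H1", 1] <- 1.0
  expect_error(synthetic_config(indicators = ind), "strictly")
  expect_error(synthetic_config(hospital_sizes = c(H1 = -5)), "positive")
})

test_that("with zero effects the TP rate matches the independence product", {
  cfg <- synthetic_config(
    seed = 17,
    hospital_sizes = c(H1 = 50000),
    indicators = rbind(H1 = c(malnutrition = 0.95,
                              surgery_within_24h = 0.69,
                              orthogeriatric = 0.80,
                              certified_surgeon = 0.92)),
    casemix_effects = list(),
    missingness = c(sex = 0))
  cfg$outcomes$complication$hospital <- c(H1 = 0)
  cfg$outcomes$prolonged$hospital <- c(H1 = 0)
  sim <- generate_registry(cfg)
  p <- prod(c(0.95, 0.69, 0.80, 0.92))   # 0.482
  rate <- mean(sim$truth$patients$textbook_true)
  se <- sqrt(p * (1 - p) / 50000)
  expect_lt(abs(rate - p), 3 * se)
})

test_that("default per-hospital TP rates bracket the low-to-high study range", {
  sc <- scored_cohort(seed = 2026)
  cs <- compliance_summary(sc)
  rates <- cs$rate_percent[cs$stratum != "overall"]
  expect_lte(min(rates), 38.1)
  expect_gte(max(rates), 75.6)
})

test_that("time-to-surgery draws are consistent with the 24h status", {
  sim <- generate_registry(synthetic_config(seed = 19))
  iv <- derive_intervals(sim$records)
  met <- sim$truth$patients$surgery_within_24h_met
  expect_true(all(iv$time_to_surgery_hours[met] <= 24))
  expect_true(all(iv$time_to_surgery_hours[!met] > 24))
  expect_true(all(iv$time_to_surgery_hours <= 336))
})

test_that("missingness injection is MCAR at the configured rate", {
  sim <- generate_registry(synthetic_config(
    seed = 23,
    hospital_sizes = c(H1 = 10000),
    indicators = rbind(H1 = c(malnutrition = 0.95,
                              surgery_within_24h = 0.7,
                              orthogeriatric = 0.9,
                              certified_surgeon = 0.92)),
    casemix_effects = list(),
    missingness = c(sex = 0)))
  # rate 0 everywhere leaves the table untouched
  masked0 <- inject_missingness(sim$records, c(asa_class = 0), seed = 1)
  expect_identical(masked0, sim$records)
  masked <- inject_missingness(sim$records, c(asa_class = 0.03), seed = 1)
  k <- sum(is.na(masked$asa_class))
  expect_lt(abs(k - 300), 3 * sqrt(10000 * 0.03 * 0.97))
  expect_error(inject_missingness(sim$records, c(asa_class = 1.5)), "0, 1")
  expect_error(inject_missingness(sim$records, c(nope = 0.1)), "nope")
})

test_that("pipeline closure: no record lost without planted violations", {
  sim <- generate_registry(synthetic_config(seed = 29))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(sim$records, path)
  parsed <- parse_registry(path)
  expect_equal(nrow(parsed$issues), 0L)
  el <- select_eligible(clean_records(parsed$records))
  expect_equal(nrow(el$records), nrow(sim$records))
  expect_equal(sum(el$tally), 0L)
})

test_that("outcome-model coefficients are recovered from a large cohort", {
  cfg <- synthetic_config(
    seed = 37,
    hospital_sizes = c(H1 = 4000, H2 = 4000, H3 = 4000, H4 = 4000,
                       H5 = 4000))
  sim <- generate_registry(cfg)
  sc <- score_textbook(select_eligible(clean_records(sim$records))$records)
  sc$age_c <- sc$age_years - 84
  fit <- fit_logistic(sc, "complication_any",
                      c("textbook", "age_c", "asa_class", "katz6_adl",
                        "hospital_id"))
  est <- with(fit$terms, setNames(estimate, paste0(term, level)))
  truth <- cfg$outcomes$complication
  expect_lt(abs(est[["textbook"]] - truth$textbook), 0.1)
  expect_lt(abs(est[["age_c"]] - truth$age_c), 0.1)
  expect_lt(abs(est[["asa_classasa34"]] - truth$asa34), 0.1)
  expect_lt(abs(est[["katz6_adl"]] - truth$katz), 0.1)
  for (h in c("H1", "H2", "H3", "H5")) {
    expect_lt(abs(est[[paste0("hospital_id", h)]] - truth$hospital[[h]]), 0.1)
  }
  expect_lt(abs(fit$intercept - truth$intercept), 0.1)
})
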
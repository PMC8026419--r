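test_that("O/E arithmetic and the O=E interval reproduce closed forms", {
  # printed-table worked rows
  expect_equal(round(compute_oe_ratio(117, 177.35), 2), 0.66)
  expect_equal(round(compute_oe_ratio(155, 117.75), 2), 1.32)
  ci1 <- oe_confidence_interval(177.35, 1.96)
  expect_equal(round(ci1$ci_low, 2), 0.86)
  expect_equal(round(ci1$ci_high, 2), 1.15)
  ci2 <- oe_confidence_interval(117.75, 1.96)
  expect_equal(round(ci2$ci_low, 2), 0.83)
  expect_equal(round(ci2$ci_high, 2), 1.19)
  # identities and errors
  expect_equal(compute_oe_ratio(50, 50), 1)
  z0 <- oe_confidence_interval(10, 0)
  expect_equal(c(z0$ci_low, z0$ci_high), c(1, 1))
  expect_error(compute_oe_ratio(10, 0), "positive")
  expect_error(oe_confidence_interval(-1), "positive")
})

test_that("interval narrows with E and agrees with the count-scale rule", {
  E <- c(2, 10, 50, 200, 1000)
  ci <- oe_confidence_interval(E, 1.96)
  widths <- ci$ci_high - ci$ci_low
  expect_true(all(diff(widths) < 0))
  expect_lt(abs(ci$ci_low[5] - 1), 0.07)
  expect_lt(abs(ci$ci_high[5] - 1), 0.07)
  # classification == "O outside (sqrt(E) +/- z/2)^2" restated on counts
  for (e in E) {
    for (o in unique(pmax(0, round(e + c(-3, -1, 0, 1, 3) * sqrt(e))))) {
      cls <- classify_hospital(o / e, (sqrt(e) - 0.98)^2 / e,
                               (sqrt(e) + 0.98)^2 / e)
      outside <- o < (sqrt(e) - 0.98)^2 | o > (sqrt(e) + 0.98)^2
      expect_equal(cls != "as_expected", outside)
    }
  }
})

test_that("hospital classification matches the worked examples", {
  expect_equal(classify_hospital(0.66, 0.86, 1.15), "worse")
  expect_equal(classify_hospital(1.32, 0.83, 1.19), "better")
  expect_equal(classify_hospital(1.00, 0.86, 1.15), "as_expected")
  expect_equal(classify_hospital(0.86, 0.86, 1.15), "as_expected") # boundary
})

test_that("screening runs the declared test per variable and respects alpha", {
  sc <- scored_cohort(seed = 31)
  scr <- screen_casemix(sc)
  expect_setequal(scr$test[scr$variable == "age_years"], "t_test")
  expect_setequal(scr$test[scr$variable == "katz6_adl"], "mann_whitney")
  expect_setequal(scr$test[scr$variable == "asa_class"], "chi_square")
  expect_equal(scr$selected, !is.na(scr$p_value) & scr$p_value < 0.10)
  # the generator's only case-mix effect on compliance is through ASA
  expect_true(scr$selected[scr$variable == "asa_class"])
})

test_that("screening on two identical groups selects nothing", {
  base <- tiny_cohort()
  dup <- rbind(base, base, base, base)
  dup$patient_id <- paste0("P", seq_len(nrow(dup)))
  dup$textbook <- rep(c(TRUE, FALSE), each = nrow(base) * 2)
  scr <- suppressWarnings(screen_casemix(dup))
  expect_false(any(scr$selected, na.rm = TRUE))
})

test_that("screening is monotone in alpha", {
  sc <- scored_cohort(seed = 32)
  s10 <- screen_casemix(sc, config = analysis_config(screening_alpha = 0.10))
  s30 <- screen_casemix(sc, config = analysis_config(screening_alpha = 0.30))
  expect_true(all(s30$selected[s10$selected]))
})

test_that("a planted strong ASA effect is the variable screened in", {
  hits <- 0L
  reps <- 20L
  for (seed in seq_len(reps)) {
    cfg <- synthetic_config(
      seed = 100 + seed,
      hospital_sizes = c(H1 = 1000, H2 = 1000),
      indicators = rbind(H1 = c(malnutrition = 0.97,
                                surgery_within_24h = 0.70,
                                orthogeriatric = 0.92,
                                certified_surgeon = 0.95),
                         H2 = c(malnutrition = 0.97,
                                surgery_within_24h = 0.70,
                                orthogeriatric = 0.92,
                                certified_surgeon = 0.95)),
      casemix_effects = list(surgery_within_24h = c(asa34 = -0.9)))
    sim <- generate_registry(cfg)
    sc <- score_textbook(select_eligible(clean_records(sim$records))$records)
    scr <- screen_casemix(sc, c("age_years", "sex", "asa_class",
                                "katz6_adl", "living_situation"))
    if (scr$selected[scr$variable == "asa_class"]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("expected counts equal hand-summed predicted probabilities", {
  sc <- scored_cohort(seed = 33)
  model <- fit_logistic(sc, "textbook", c("asa_class", "age_years"))
  ec <- expected_counts(model, sc)
  probs <- tpaudit:::fitted_probs(model)
  hand <- tapply(probs, as.character(model$hospital_id), sum)
  expect_equal(ec$expected, as.vector(hand[ec$hospital_id]),
               tolerance = 1e-6)
  # intercept-only: E_h = n_h * overall rate (on the prediction set)
  m0 <- fit_logistic(sc, "textbook")
  ec0 <- expected_counts(m0, sc)
  expect_equal(ec0$expected, ec0$n_pred * mean(sc$textbook), tolerance = 1e-6)
})

test_that("expected counts can cover all patients via imputation", {
  sc <- scored_cohort(seed = 33)
  cfg <- analysis_config(expected_prediction = "all_imputed")
  model <- fit_logistic(sc, "textbook", c("asa_class", "katz6_adl"), cfg)
  ec <- expected_counts(model, sc, cfg)
  expect_equal(sum(ec$n_pred), nrow(sc))
})

test_that("a single-hospital intercept model benchmarks as as_expected", {
  cfg <- synthetic_config(
    seed = 44, hospital_sizes = c(H1 = 500),
    indicators = rbind(H1 = c(malnutrition = 0.95,
                              surgery_within_24h = 0.7,
                              orthogeriatric = 0.9,
                              certified_surgeon = 0.93)),
    casemix_effects = list(),
    missingness = c(sex = 0),
    outcomes = synthetic_config(seed = 1)$outcomes[
      c("complication", "prolonged", "mortality")])
  cfg$outcomes$complication$hospital <- c(H1 = 0)
  cfg$outcomes$prolonged$hospital <- c(H1 = 0)
  sim <- generate_registry(cfg)
  sc <- score_textbook(select_eligible(clean_records(sim$records))$records)
  b <- suppressWarnings(benchmark_hospitals(sc))
  # with an intercept-bearing ML fit, sum of fitted probabilities = O
  expect_equal(b$table$expected, b$table$observed, tolerance = 1e-6)
  expect_equal(b$table$classification, "as_expected")
})

test_that("a hospital with sharply lower compliance is flagged worse", {
  worse <- 0L
  reps <- 11L
  for (seed in seq_len(reps)) {
    cfg <- synthetic_config(seed = 300 + seed)
    cfg$indicators["H3", "surgery_within_24h"] <- 0.40  # -0.25 absolute TP shift
    sim <- generate_registry(cfg)
    sc <- score_textbook(select_eligible(clean_records(sim$records))$records)
    b <- benchmark_hospitals(sc)
    cls <- b$table$classification[b$table$hospital_id == "H3"]
    if (cls == "worse") worse <- worse + 1L
  }
  expect_gt(worse / reps, 0.5)
})
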
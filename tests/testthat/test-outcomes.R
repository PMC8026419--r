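test_that("2x2 odds ratio and Wald interval match closed forms", {
  # worked contrast: complication events 284/753 exposed vs 284/617 unexposed
  res <- two_by_two_or(two_by_two(284, 469, 284, 333))
  expect_equal(round(res$or, 2), 0.71)
  expect_equal(round(res$ci_low, 2), 0.57)
  expect_equal(round(res$ci_high, 2), 0.88)
  expect_equal(two_by_two_or(two_by_two(7, 7, 7, 7))$or, 1)
  expect_equal(two_by_two_or(two_by_two(10, 20, 5, 40))$or, 4)
})

test_that("zero cells flag the CI unavailable unless Haldane is enabled", {
  res <- two_by_two_or(two_by_two(0, 20, 5, 40))
  expect_false(res$ci_available)
  expect_true(is.na(res$ci_low))
  resh <- two_by_two_or(two_by_two(0, 20, 5, 40),
                        analysis_config(haldane = TRUE))
  expect_true(resh$ci_available)
  expect_equal(resh$or, (0.5 * 40.5) / (20.5 * 5.5))
})

test_that("2x2 OR equals the univariable logistic OR for the same margins", {
  df <- data.frame(
    patient_id = seq_len(1370), hospital_id = "H1",
    textbook = rep(c(TRUE, FALSE), c(753, 617)),
    complication_any = factor(c(rep(c("yes", "no"), c(284, 469)),
                                rep(c("yes", "no"), c(284, 333))),
                              levels = c("yes", "no")))
  fit <- fit_logistic(df, "complication_any", "textbook")
  tab <- two_by_two_or(two_by_two(284, 469, 284, 333))
  expect_lt(abs(fit$terms$or - tab$or), 1e-6)
  expect_lt(abs(fit$terms$ci_low - tab$ci_low), 1e-6)
  expect_lt(abs(fit$terms$ci_high - tab$ci_high), 1e-6)
  # rate partition reproduces the printed group rates
  t2 <- two_by_two(284, 469, 284, 333)
  expect_equal(round(100 * t2$event_rate_exposed, 1), 37.7)
  expect_equal(round(100 * t2$event_rate_unexposed, 1), 46.0)
})

test_that("prolonged-stay flag is inclusive at the cutoff and missing-safe", {
  x <- clean_records(tiny_cohort())
  x$postop_stay_days <- c(6.0, 5.9, NA)
  fl <- prolonged_stay_flag(x)
  expect_equal(fl, c(TRUE, FALSE, NA))
})

test_that("baseline table applies the declared tests and the missing rule", {
  sc <- scored_cohort(seed = 51)
  bl <- baseline_comparison(sc)
  asa <- bl[bl$variable == "asa_class", ]
  expect_equal(asa$test[1], "chi_square")
  expect_true(is.finite(asa$p_value[1]))
  age <- bl[bl$variable == "age_years", ]
  expect_match(age$overall[1], "^[0-9.]+ \\([0-9.]+\\)$")  # mean (SD)
  katz <- bl[bl$variable == "katz6_adl", ]
  expect_equal(katz$test[1], "mann_whitney")
  # chi-square statistic against the hand formula on a 2x2 fixture
  df <- data.frame(patient_id = 1:60, hospital_id = "H1",
                   textbook = rep(c(TRUE, FALSE), each = 30),
                   sex = factor(rep(c("female", "male", "female", "male"),
                                    c(20, 10, 10, 20)),
                                c("female", "male")))
  obs <- table(df$sex, df$textbook)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expected)^2 / expected)
  p_hand <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  bl2 <- baseline_comparison(df, variables = "sex")
  expect_equal(bl2$p_value[1], p_hand, tolerance = 1e-6)
})

test_that("identical groups show no significant baseline differences", {
  base <- scored_cohort(seed = 52)
  base$textbook <- rep(c(TRUE, FALSE), length.out = nrow(base))
  # duplicate so the two groups are literally identical
  dup <- rbind(base, base)
  dup$textbook <- rep(c(TRUE, FALSE), each = nrow(base))
  dup$patient_id <- paste0("P", seq_len(nrow(dup)))
  bl <- suppressWarnings(baseline_comparison(dup))
  p <- bl$p_value[!is.na(bl$p_value)]
  expect_true(all(p > 0.95))
})

test_that("outcome analysis screens, forces covariates and excludes missing outcomes", {
  sc <- scored_cohort(seed = 53)
  rep_c <- analyze_outcome(sc, "complication_any")
  terms <- unique(rep_c$multivariable$terms$term)
  expect_true(all(c("textbook", "treatment", "hospital_id") %in% terms))
  expect_setequal(setdiff(terms, c("textbook", "treatment", "hospital_id")),
                  rep_c$screening$variable[rep_c$screening$selected])
  expect_equal(rep_c$n_missing_outcome,
               sum(is.na(sc$complication_any)))
  # screened set for the generator's complication model: age and ASA carry
  # the signal (Katz effect is tiny)
  expect_true(all(c("age_years", "asa_class") %in%
                    rep_c$screening$variable[rep_c$screening$selected]))
})

test_that("null textbook effect yields nominal CI coverage", {
  reps <- 60L
  cover <- 0L
  for (seed in seq_len(reps)) {
    ind2 <- synthetic_config(seed = 1)$indicators[c("H1", "H2"), ]
    cfg <- synthetic_config(seed = 700 + seed,
                            hospital_sizes = c(H1 = 400, H2 = 400),
                            indicators = ind2)
    cfg$outcomes$complication$textbook <- 0
    cfg$outcomes$complication$hospital <- c(H1 = 0, H2 = 0)
    cfg$outcomes$prolonged$hospital <- c(H1 = 0, H2 = 0)
    sim <- generate_registry(cfg)
    sc <- score_textbook(select_eligible(clean_records(sim$records))$records)
    fit <- fit_logistic(sc, "complication_any", "textbook")
    if (fit$terms$ci_low <= 1 && fit$terms$ci_high >= 1) cover <- cover + 1L
  }
  expect_gt(cover / reps, 0.87)
  expect_lt(cover / reps, 1.0 + 1e-9)
})

test_that("mortality summary reproduces printed-scale arithmetic and the EPV verdict", {
  # a fixture with exactly 37 deaths among 1332 analysable patients
  df <- data.frame(
    patient_id = seq_len(1334), hospital_id = rep(c("H1", "H2", "H3", "H4", "H5"),
                                                  length.out = 1334),
    textbook = rep(c(TRUE, FALSE), length.out = 1334),
    treatment = factor("osteosynthesis", c("osteosynthesis", "prosthesis")),
    age_years = 84L, sex = factor("female", c("female", "male")),
    asa_class = factor("asa34", c("asa12", "asa34")),
    dementia = factor("no", c("no", "yes", "unknown")),
    katz6_adl = 1L,
    living_situation = factor("independent",
                              c("independent", "institutionalized")),
    in_hospital_death = factor(c(rep("yes", 37), rep("no", 1295),
                                 NA, NA), levels = c("yes", "no")))
  ms <- suppressWarnings(mortality_summary(df))
  expect_equal(ms$overall$deaths, 37)
  expect_equal(ms$overall$n, 1332)
  expect_equal(ms$overall$rate_percent, 2.8)
  expect_equal(ms$n_missing_outcome, 2)
  # 37 events cannot support >= 6 parameters at 10 events per parameter
  expect_gte(ms$planned_parameters, 6)
  expect_equal(ms$verdict, "descriptive_only")
  expect_equal(ms$event_deficit, 10 * ms$planned_parameters - 37)
  # zero deaths: 0%, descriptive-only
  df$in_hospital_death[] <- "no"
  ms0 <- suppressWarnings(mortality_summary(df))
  expect_equal(ms0$overall$rate_percent, 0)
  expect_equal(ms0$verdict, "descriptive_only")
})
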
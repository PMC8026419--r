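#' Flatten an outcome report to a table
#'
#' Mirrors the published regression-table layout: one row per term level
#' with univariable OR/CI/p and, where the term entered the multivariable
#' model, adjusted OR/CI/p. Ratios rounded at the configured places.
#'
#' @param report a \code{tp_outcome_report} from \code{\link{analyze_outcome}}.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame ready for CSV export.
#' @export
outcome_report_table <- function(report, config = analysis_config()) {
  assert_config(config)
  rr <- config$round_ratios
  grab <- function(model, prefix) {
    t <- model$terms
    out <- data.frame(term = t$term, level = t$level,
                      reference = t$reference, stringsAsFactors = FALSE)
    out[[paste0(prefix, "_or")]] <- round_half_up(t$or, rr)
    out[[paste0(prefix, "_ci_low")]] <- round_half_up(t$ci_low, rr)
    out[[paste0(prefix, "_ci_high")]] <- round_half_up(t$ci_high, rr)
    out[[paste0(prefix, "_p")]] <- signif(t$p_value, 3)
    out
  }
  uni <- do.call(rbind, lapply(report$univariable, grab, prefix = "uni"))
  rownames(uni) <- NULL
  multi <- grab(report$multivariable, "multi")
  merge(uni, multi, by = c("term", "level", "reference"), all.x = TRUE,
        sort = FALSE)
}

#' Rounded benchmark table
#'
#' @param bench a \code{tp_benchmark}.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame with observed rate, expected count, O/E ratio and CI
#'   bounds rounded at the configured places (classification from unrounded
#'   values).
#' @export
benchmark_table <- function(bench, config = analysis_config()) {
  assert_config(config)
  tab <- bench$table
  tab$observed_rate <- round_half_up(tab$observed_rate, config$round_percent)
  tab$expected <- round_half_up(tab$expected, config$round_ratios)
  tab$oe_ratio <- round_half_up(tab$oe_ratio, config$round_ratios)
  tab$ci_low <- round_half_up(tab$ci_low, config$round_ratios)
  tab$ci_high <- round_half_up(tab$ci_high, config$round_ratios)
  tab
}

regression_to_list <- function(model) {
  if (is.null(model)) return(NULL)
  list(outcome = model$outcome, intercept = model$intercept,
       n_used = model$n_used, events = model$events,
       converged = model$converged, terms = model$terms)
}

write_manifest <- function(path, seed = NULL, inputs = NULL, counts = NULL,
                           config = NULL) {
  manifest <- list(
    package = "tpaudit",
    version = as.character(utils::packageVersion("tpaudit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = seed,
    inputs = inputs,
    row_counts = counts,
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Simulate a registry to disk
#'
#' Generates a synthetic registry and writes \code{registry.csv}, the
#' ground-truth sidecar \code{truth.json} and a run manifest into
#' \code{out_dir}. Deterministic: the same configuration and seed yield
#' byte-identical files.
#'
#' @param out_dir output directory (created if absent).
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed; overrides \code{config$seed} when given.
#' @return invisibly, the generated \code{records}/\code{truth} list.
#' @export
run_simulate <- function(out_dir, config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) stop_tp("a seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_registry(config)
  reg_path <- file.path(out_dir, "registry.csv")
  write_registry(sim$records, reg_path)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 seed = config$seed,
                 inputs = list(),
                 counts = list(generated = nrow(sim$records)),
                 config = config[setdiff(names(config), "indicators")])
  invisible(sim)
}

#' Run the full audit pipeline on a registry file
#'
#' Parses, cleans and eligibility-filters the registry, scores the
#' textbook-process composite, and writes the full report bundle:
#' baseline comparison, cumulative funnel, case-mix adjusted hospital
#' benchmark, complication and prolonged-stay regression tables, mortality
#' summary, screening decisions, a run manifest and a human-readable log of
#' exclusions and model diagnostics. A non-convergent outcome model is
#' flagged in the bundle rather than aborting the run.
#'
#' @param registry_path path to a registry CSV.
#' @param out_dir output directory (created if absent).
#' @param config an \code{\link{analysis_config}}.
#' @return invisibly, a list with every computed result (\code{scored},
#'   \code{eligibility}, \code{baseline}, \code{funnel}, \code{benchmark},
#'   \code{complications}, \code{prolonged_stay}, \code{mortality},
#'   \code{issues}).
#' @export
run_analyze <- function(registry_path, out_dir,
                        config = analysis_config()) {
  assert_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parsed <- parse_registry(registry_path, config)
  cleaned <- clean_records(parsed$records, config)
  elig <- select_eligible(cleaned, config)
  if (nrow(elig$records) == 0) stop_tp("no eligible patients in registry")
  scored <- score_textbook(elig$records, config)
  status <- evaluate_indicators(elig$records, config)

  baseline <- baseline_comparison(scored, config = config)
  funnel <- cumulative_funnel(status, config)
  compliance <- compliance_summary(scored, config)
  bench <- benchmark_hospitals(scored, config = config)
  fit_or_flag <- function(expr) {
    tryCatch(expr, error = function(e) structure(list(error = conditionMessage(e)),
                                                 class = "tp_failed_model"))
  }
  compl <- fit_or_flag(analyze_outcome(scored, "complication_any", config))
  plos <- fit_or_flag(analyze_outcome(scored, "prolonged_stay", config))
  mort <- mortality_summary(scored, config)

  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE, na = "")
  w(as.data.frame(baseline), "baseline.csv")
  w(as.data.frame(funnel), "funnel.csv")
  w(compliance, "compliance.csv")
  w(benchmark_table(bench, config), "benchmark.csv")
  w(bench$screening, "screening_textbook.csv")
  for (nm in c("complications", "prolonged_stay")) {
    rep_obj <- if (nm == "complications") compl else plos
    if (!inherits(rep_obj, "tp_failed_model")) {
      w(outcome_report_table(rep_obj, config), paste0("outcome_", nm, ".csv"))
    }
  }
  jsonlite::write_json(
    list(benchmark_model = regression_to_list(bench$model),
         complications = if (!inherits(compl, "tp_failed_model"))
           regression_to_list(compl$multivariable) else compl,
         prolonged_stay = if (!inherits(plos, "tp_failed_model"))
           regression_to_list(plos$multivariable) else plos,
         mortality = mort[c("overall", "by_group", "by_hospital",
                            "planned_parameters", "verdict",
                            "event_deficit")]),
    file.path(out_dir, "models.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

  log_lines <- c(
    sprintf("rows parsed: %d (issues: %d)", nrow(parsed$records),
            nrow(parsed$issues)),
    sprintf("eligible: %d", nrow(elig$records)),
    sprintf("excluded by rule: %s",
            paste(names(elig$tally), elig$tally, sep = "=", collapse = ", ")),
    sprintf("textbook process: %d/%d", sum(scored$textbook), nrow(scored)),
    sprintf("case-mix adjusted for: %s",
            paste(bench$screening$variable[bench$screening$selected],
                  collapse = ", ")),
    sprintf("mortality verdict: %s", mort$verdict))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 inputs = list(registry = unname(tools::md5sum(registry_path))),
                 counts = list(parsed = nrow(parsed$records),
                               eligible = nrow(elig$records),
                               textbook = sum(scored$textbook)),
                 config = unclass(config))
  invisible(list(scored = scored, eligibility = elig, baseline = baseline,
                 funnel = funnel, compliance = compliance, benchmark = bench,
                 complications = compl, prolonged_stay = plos,
                 mortality = mort, issues = parsed$issues))
}
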
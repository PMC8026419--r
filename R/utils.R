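# Internal helpers.

# round half away from zero at `digits` places (table-rendering convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_tristate <- function(x, levels = c("met", "not_met")) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  x[bad] <- NA_character_
  factor(x, levels = levels)
}

# fraction of NA entries in a vector
na_frac <- function(x) mean(is.na(x))

# mode of a factor/character (ties broken by level order); median for numerics
impute_value <- function(x) {
  if (is.numeric(x)) return(stats::median(x, na.rm = TRUE))
  tab <- table(x)
  names(tab)[which.max(tab)]
}

stop_tp <- function(...) stop(..., call. = FALSE)

assert_config <- function(config) {
  if (!inherits(config, "tp_config")) {
    stop_tp("`config` must be created by analysis_config()")
  }
  invisible(config)
}

fmt_pct <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)
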
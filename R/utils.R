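# condition helpers: every error carries class "paravar_error" plus a
# specific subclass so callers (and the CLI wrapper) can map failures to
# exit codes without string-matching messages.

stop_paravar <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "paravar_error"), ...)
}

stop_format <- function(message, ...) stop_paravar(message, "paravar_format_error", ...)
stop_reference <- function(message, ...) stop_paravar(message, "paravar_reference_error", ...)
stop_alphabet <- function(message, ...) stop_paravar(message, "paravar_alphabet_error", ...)
stop_index <- function(message, ...) stop_paravar(message, "paravar_index_error", ...)
stop_coordinate <- function(message, ...) stop_paravar(message, "paravar_coordinate_error", ...)
stop_schema <- function(message, ...) stop_paravar(message, "paravar_schema_error", ...)
stop_value <- function(message, ...) stop_paravar(message, "paravar_value_error", ...)
stop_parse <- function(message, ...) stop_paravar(message, "paravar_parse_error", ...)
stop_consistency <- function(message, ...) stop_paravar(message, "paravar_consistency_error", ...)
stop_mismatch <- function(message, ...) stop_paravar(message, "paravar_mismatch_error", ...)
stop_profile <- function(message, ...) stop_paravar(message, "paravar_profile_error", ...)
stop_stats <- function(message, ...) stop_paravar(message, "paravar_stats_error", ...)
stop_config <- function(message, ...) stop_paravar(message, "paravar_config_error", ...)
stop_sampling <- function(message, ...) stop_paravar(message, "paravar_sampling_error", ...)

# age strings such as "7 weeks", "3 months 22 days", "8 years" -> days.
# Used only for descriptive tabulation of cohort fixtures; 1 month is taken
# as 30.44 days (mean Gregorian month).
#' Parse human-readable age strings to days
#'
#' Converts strings like `"7 weeks"`, `"3 months 22 days"` or `"8 years"` to
#' a number of days, using 1 year = 365.25 days, 1 month = 30.44 days and
#' 1 week = 7 days. Intended for descriptive tabulation of cohort tables,
#' not for precise survival arithmetic.
#'
#' @param x Character vector of age descriptions.
#' @return Numeric vector of ages in days (`NA` where unparseable).
#' @examples
#' parse_age_days(c("7 weeks", "3 months 22 days", "8 years"))
#' @export
parse_age_days <- function(x) {
  unit_days <- c(year = 365.25, month = 30.44, week = 7, day = 1)
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(NA_real_)
    }
    m <- stringr::str_match_all(
      tolower(s),
      "(\\d+(?:\\.\\d+)?)\\s*(year|month|week|day)s?"
    )[[1]]
    if (nrow(m) == 0) {
      return(NA_real_)
    }
    sum(as.numeric(m[, 2]) * unit_days[m[, 3]])
  }, numeric(1), USE.NAMES = FALSE)
}
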
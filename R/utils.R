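# Internal helpers shared across modules.

# Days per month used for every duration reported in months. The source data
# carry calendar dates; all arithmetic is done in whole days and converted
# once, at the reporting boundary, with the mean Gregorian month length.
DAYS_PER_MONTH <- 30.4375

#' Convert a day count to months
#'
#' All internal survival arithmetic is in whole days; durations are reported
#' in months using the mean Gregorian month length of 30.4375 days.
#'
#' @param days Numeric vector of day counts.
#' @return Numeric vector of months.
#' @export
#' @examples
#' days_to_months(365) # 11.99 months
days_to_months <- function(days) {
  as.numeric(days) / DAYS_PER_MONTH
}

#' Emit a timestamped log message to standard error
#'
#' Logging is silent unless `options(irscore.verbose = TRUE)` is set.
#'
#' @param ... Passed to [sprintf()] (format string first).
#' @return Invisibly, the formatted message.
#' @export
irs_log <- function(...) {
  msg <- sprintf(...)
  if (isTRUE(getOption("irscore.verbose", FALSE))) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), msg)
  }
  invisible(msg)
}

# stop() with a condition class so callers/tests can distinguish error kinds
irs_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "irscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# checks that `x` is a data frame containing `cols`; errors naming the missing
assert_columns <- function(x, cols, what = "input") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    irs_abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      "irscore_schema_error"
    )
  }
  invisible(x)
}

# seeded evaluation that does not disturb the caller's RNG stream
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
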
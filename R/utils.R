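# Internal helpers shared across modules.

DAYS_PER_YEAR <- 365.25

#' Floored age in whole years between two dates
#'
#' Ages are measured in days and converted with a 365.25-day year, then
#' floored, so an individual aged 363 days is in age class 0 and one aged
#' 366 days is in age class 1.
#'
#' @param birth,at `Date` vectors (recycled).
#' @return Integer vector of floored ages; negative when `at` precedes `birth`.
#' @export
age_class_at <- function(birth, at) {
  as.integer(floor(as.numeric(at - birth) / DAYS_PER_YEAR))
}

# Fractional age in years (365.25-day years).
age_years_at <- function(birth, at) {
  as.numeric(at - birth) / DAYS_PER_YEAR
}

# December 31 of a calendar year.
year_end <- function(year) as.Date(sprintf("%d-12-31", year))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stopifnot() with a formatted message.
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
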
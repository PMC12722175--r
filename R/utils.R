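#' @keywords internal
"_PACKAGE"

# mg/mmol -> mg/g conversion factor for creatinine-indexed ratios
MGMMOL_TO_MGG <- 8.84

DIPSTICK_LEVELS <- c("neg", "trace", "1+", "2+", "3+")

DAYS_PER_YEAR <- 365.25

#' Convert a horizon in years to whole days
#'
#' Horizons are truncated to whole days (floor of 365.25 * years) so that
#' follow-up stays integer-valued and leap years do not shift the boundary.
#'
#' @param horizon_years horizon in years
#' @return integer number of days
#' @export
horizon_days <- function(horizon_years) {
  stopifnot(is.numeric(horizon_years), horizon_years > 0)
  floor(DAYS_PER_YEAR * horizon_years)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_field <- function(ok, field, what) {
  if (!isTRUE(all(ok))) {
    stop_input("invalid configuration: field '%s' %s", field, what)
  }
}

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

as_date <- function(x) as.Date(x)

# stable text formatting for report files (byte-identical reruns)
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
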
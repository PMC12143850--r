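#' @importFrom stats rnorm runif rpois sd quantile fivenum pt runmed filter
#' @importFrom utils unzip head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even (0.0125 -> 0.012); reported
#' thresholds and percentages in this package follow the usual manuscript
#' convention of rounding half up (0.0125 -> 0.013).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# numeric UTC seconds -> POSIXct
as_posix <- function(t, tz = "UTC") {
  as.POSIXct(t, origin = "1970-01-01", tz = tz)
}

# seconds since local midnight for a numeric UTC time
local_seconds_of_day <- function(t, tz) {
  lt <- as.POSIXlt(as_posix(t), tz = tz)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# local calendar date (as Date) of a numeric UTC time
local_date <- function(t, tz) {
  as.Date(as.POSIXlt(as_posix(t), tz = tz))
}

# numeric UTC time of `sod` seconds after local midnight on local date `date`
time_at_local <- function(date, sod, tz) {
  midnight <- as.POSIXct(format(date), tz = tz)
  as.numeric(midnight) + sod
}

# overlap length of [a1,a2) and [b1,b2)
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
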
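#' Map calendar dates to biweekly composite periods
#'
#' The record uses 24 compositing periods per year: half "a" of each month
#' covers days 1-15 and half "b" day 16 through the month end (leap days
#' included). The within-year ordinal is `2*(month-1) + 1` for half "a" and
#' `+2` for half "b".
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @return a tibble with columns `year`, `month`, `half` ("a"/"b") and
#'   `ordinal` (1-24).
#' @examples
#' biweekly_index_of(as.Date(c("1982-01-15", "1982-02-28", "2000-02-29")))
#' @export
biweekly_index_of <- function(date) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  month <- lt$mon + 1L
  day <- lt$mday
  half <- ifelse(day <= 15L, "a", "b")
  tibble::tibble(
    year = lt$year + 1900L,
    month = month,
    half = half,
    ordinal = 2L * (month - 1L) + ifelse(half == "a", 1L, 2L)
  )
}

#' Biweekly time axis over a span of years
#'
#' @param start_year,end_year inclusive year range.
#' @return tibble with `year`, `month`, `half`, `ordinal` (period-of-year,
#'   1-24), `index` (1..n over the record) and `mid_date`, the representative
#'   mid-period calendar date used for solar geometry.
#' @export
biweekly_seq <- function(start_year, end_year) {
  years <- seq.int(start_year, end_year)
  out <- tidyr::expand_grid(year = years, month = 1:12, half = c("a", "b"))
  out$ordinal <- 2L * (out$month - 1L) + ifelse(out$half == "a", 1L, 2L)
  out <- dplyr::arrange(out, .data$year, .data$ordinal)
  out$index <- seq_len(nrow(out))
  last_day <- function(y, m) {
    d <- as.Date(sprintf("%04d-%02d-01", y, m))
    as.integer(format(seq(d, by = "1 month", length.out = 2)[2] - 1, "%d"))
  }
  mid_day <- ifelse(out$half == "a", 8L,
                    16L + (mapply(last_day, out$year, out$month) - 16L) %/% 2L)
  out$mid_date <- as.Date(sprintf("%04d-%02d-%02d", out$year, out$month, mid_day))
  out
}

# day-of-year of the representative date of each period
period_mid_doy <- function(time) as.integer(format(time$mid_date, "%j"))

# label "<YYYYMM><a|b>" used in product file names
period_label <- function(time) sprintf("%04d%02d%s", time$year, time$month, time$half)
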
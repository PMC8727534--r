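#' Parse FAERS partial dates
#'
#' FAERS date fields (\code{FDA_DT}, \code{EVENT_DT}, \code{START_DT}) are
#' numeric strings of 4, 6 or 8 digits: \code{YYYY}, \code{YYYYMM} or
#' \code{YYYYMMDD}. Precision is preserved explicitly and never imputed:
#' a month-precision onset date cannot enter a day-resolution time-to-onset
#' calculation, it is excluded instead.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @return data.frame with integer columns \code{year}, \code{month},
#'   \code{day} (NA where unknown) and a character \code{precision} in
#'   \code{c("day","month","year","missing")}. Unparseable fields are
#'   missing; an impossible month or day drops that component (and finer
#'   ones), downgrading the precision rather than discarding the whole date.
#' @export
#' @examples
#' parse_faers_date(c("20200315", "201503", "2015", "", "20200230"))
parse_faers_date <- function(x) {
  x <- as.character(x)
  x <- trimws(ifelse(is.na(x), "", x))
  x[!grepl("^[0-9]{4}([0-9]{2})?([0-9]{2})?$", x)] <- ""
  n <- nchar(x)
  year <- ifelse(n >= 4, as.integer(substr(x, 1, 4)), NA_integer_)
  month <- ifelse(n >= 6, as.integer(substr(x, 5, 6)), NA_integer_)
  day <- ifelse(n == 8, as.integer(substr(x, 7, 8)), NA_integer_)

  bad_month <- !is.na(month) & (month < 1 | month > 12)
  month[bad_month] <- NA_integer_
  day[bad_month] <- NA_integer_
  # validate full dates via the calendar
  full <- !is.na(day)
  if (any(full)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", year[full], month[full],
                         pmin(pmax(day[full], 1), 31)), format = "%Y-%m-%d")
    bad_day <- is.na(d) | day[full] < 1 | day[full] > 31
    day[full][bad_day] <- NA_integer_
  }
  precision <- ifelse(is.na(year), "missing",
               ifelse(is.na(month), "year",
               ifelse(is.na(day), "month", "day")))
  data.frame(year = year, month = month, day = day,
             precision = precision, stringsAsFactors = FALSE)
}

# Date vector from parsed components; NA unless day precision.
partial_as_date <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  i <- pd$precision == "day"
  if (any(i)) {
    out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i], pd$day[i]))
  }
  out
}

# compact YYYYMMDD / YYYYMM / YYYY string from components ("" when missing)
format_partial_date <- function(year, month, day) {
  ifelse(is.na(year), "",
  ifelse(is.na(month), sprintf("%04d", year),
  ifelse(is.na(day), sprintf("%04d%02d", year, month),
         sprintf("%04d%02d%02d", year, month, day))))
}
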
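#' Daily series container
#'
#' A `daily_series` is a data frame holding one province's aligned daily
#' vectors: calendar date, daily maximum and minimum temperature (degrees C),
#' the daily admission count for one cause, the weekday index (0 = Sunday ..
#' 6 = Saturday), a holiday flag and the daily influenza admission count used
#' as a confounder in the regression stage.
#'
#' @param province Province label (length-1 character).
#' @param dates Vector of consecutive `Date`s, strictly increasing by one day.
#' @param tmax,tmin Numeric temperature vectors (degrees C), `tmin <= tmax`
#'   elementwise where both observed; `NA` encodes missing values.
#' @param count Non-negative integer admission counts (may be `NA` before
#'   counts are simulated or read).
#' @param holiday Binary (0/1) holiday indicator.
#' @param influenza Non-negative integer influenza admission counts.
#' @return A data frame of class `daily_series` with columns `province`,
#'   `date`, `tmax`, `tmin`, `count`, `dow`, `holiday`, `influenza`.
#' @export
daily_series <- function(province, dates, tmax, tmin,
                         count = NA_integer_, holiday = 0L,
                         influenza = 0L) {
  n <- length(dates)
  ds <- data.frame(
    province = as.character(province),
    date = as.Date(dates),
    tmax = as.numeric(tmax),
    tmin = as.numeric(tmin),
    count = rep_len(suppressWarnings(as.integer(count)), n),
    dow = weekday_index(as.Date(dates)),
    holiday = rep_len(as.integer(holiday), n),
    influenza = rep_len(as.integer(influenza), n),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("daily_series", "data.frame")
  validate_daily_series(ds)
  ds
}

#' Validate a daily series
#'
#' Checks the `daily_series` invariants: equal-length columns, dates strictly
#' increasing by one day, integer non-negative counts, and `tmin <= tmax`
#' elementwise (where both are observed).
#'
#' @param ds A `daily_series`.
#' @param allow_gaps If `TRUE`, dates must only be strictly increasing (used
#'   by period splitting, which removes calendar years).
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_daily_series <- function(ds, allow_gaps = FALSE) {
  req <- c("province", "date", "tmax", "tmin", "count", "dow", "holiday",
           "influenza")
  miss <- setdiff(req, names(ds))
  if (length(miss))
    stopf("daily_series is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(ds) == 0L) stopf("daily_series is empty")
  dd <- diff(as.numeric(ds$date))
  if (!allow_gaps && any(dd != 1))
    stopf("dates must be consecutive calendar days (province %s)",
          ds$province[1])
  if (allow_gaps && any(dd <= 0))
    stopf("dates must be strictly increasing (province %s)", ds$province[1])
  ok <- !is.na(ds$count)
  if (any(ds$count[ok] < 0)) stopf("counts must be non-negative")
  ok <- !is.na(ds$influenza)
  if (any(ds$influenza[ok] < 0)) stopf("influenza counts must be non-negative")
  both <- !is.na(ds$tmax) & !is.na(ds$tmin)
  if (any(ds$tmin[both] > ds$tmax[both] + 1e-9))
    stopf("tmin exceeds tmax on %d day(s)", sum(ds$tmin[both] > ds$tmax[both]))
  invisible(ds)
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> province %s: %d days (%s .. %s)\n",
              x$province[1], nrow(x), min(x$date), max(x$date)))
  cat(sprintf("  tmax %.1f..%.1f degC, %d missing; counts: %s\n",
              suppressWarnings(min(x$tmax, na.rm = TRUE)),
              suppressWarnings(max(x$tmax, na.rm = TRUE)),
              sum(is.na(x$tmax)),
              if (all(is.na(x$count))) "not simulated/observed"
              else sprintf("mean %.1f/day", mean(x$count, na.rm = TRUE))))
  invisible(x)
}
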
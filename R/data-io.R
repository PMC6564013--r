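#' Write a multi-province panel to CSV
#'
#' Long format with columns `province,date,tmax,tmin,count,holiday,influenza`
#' and ISO-8601 dates.
#'
#' @param panel A list of `daily_series` (as from [generate_panel()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  if (inherits(panel, "daily_series")) panel <- list(panel)
  rows <- do.call(rbind, lapply(panel, function(ds)
    data.frame(province = ds$province, date = format(ds$date, "%Y-%m-%d"),
               tmax = ds$tmax, tmin = ds$tmin, count = ds$count,
               holiday = ds$holiday, influenza = ds$influenza,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-province panel from CSV
#'
#' Expects the long format written by [write_panel()]. Rows are grouped by
#' province and date-sorted; duplicate (province, date) pairs are an
#' integrity error; gaps in the date sequence are reported via a warning and
#' recorded in the `"date_gaps"` attribute. Counts are coerced to integer;
#' the weekday index is recomputed from the dates.
#'
#' @param path CSV file path.
#' @return A named list of `daily_series` (class `panel`).
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("province", "date", "tmax", "tmin", "count", "holiday", "influenza")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("panel file is missing required column(s): %s",
          paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stopf("unparseable dates in panel file")
  key <- paste(df$province, df$date)
  if (anyDuplicated(key))
    stopf("duplicate (province, date) rows: e.g. %s", key[duplicated(key)][1])
  gaps <- list()
  panel <- lapply(split(df, df$province), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    dd <- diff(as.numeric(d$date))
    if (any(dd != 1))
      gaps[[d$province[1]]] <<- d$date[which(dd != 1)]
    daily_series(province = d$province[1], dates = d$date,
                 tmax = d$tmax, tmin = d$tmin,
                 count = as.integer(round(d$count)),
                 holiday = d$holiday, influenza = d$influenza)
  })
  if (length(gaps))
    warnf("date gaps found in province(s): %s",
          paste(names(gaps), collapse = ", "))
  structure(panel, class = c("panel", "list"), date_gaps = gaps)
}

na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

impute_one_var <- function(series, var, reference) {
  x <- series[[var]]
  runs <- na_runs(x)
  log <- list()
  if (nrow(runs) == 0)
    return(list(values = x, log = NULL))
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- runs$end[k]
    len <- e - s + 1L
    if (len == 1L) {
      left <- if (s > 1) x[s - 1] else NA_real_
      right <- if (e < length(x)) x[e + 1] else NA_real_
      if (is.na(left) && is.na(right))
        stopf("unresolvable gap: no observed neighbour for %s on %s",
              var, series$date[s])
      method <- if (is.na(left) || is.na(right)) "boundary-neighbour"
      else "neighbour-mean"
      val <- mean(c(left, right), na.rm = TRUE)
      x[s] <- val
      log[[length(log) + 1L]] <- data.frame(
        province = series$province[1], date = series$date[s],
        variable = var, method = method, value = val)
    } else {
      # runs of >= 2 consecutive missing days: copy from the most
      # correlated reference station on the same dates
      if (is.null(reference))
        stopf(paste0("unresolvable gap: %d consecutive missing %s days ",
                     "starting %s and no reference series supplied"),
              len, var, series$date[s])
      idx <- match(series$date[s:e], reference$date)
      if (any(is.na(idx)) || any(is.na(reference[[var]][idx])))
        stopf("reference series does not cover %s gap starting %s",
              var, series$date[s])
      vals <- reference[[var]][idx]
      x[s:e] <- vals
      method <- if (len == 2L) "reference-station-2day" else "reference-station"
      log[[length(log) + 1L]] <- data.frame(
        province = series$province[1], date = series$date[s:e],
        variable = var, method = method, value = vals)
    }
  }
  list(values = x, log = do.call(rbind, log))
}

#' Impute missing daily temperatures
#'
#' Applies the register's imputation rules: an isolated missing day becomes
#' the mean of the two flanking days (a single neighbour at a series
#' boundary, logged distinctly); runs of two or more consecutive missing
#' days are copied from the same dates of the supplied most-correlated
#' reference station. Two-day gaps are routed to the reference rule and
#' flagged with their own method label. Observed values are never altered.
#'
#' @param series A `daily_series` with `NA`s in `tmax`/`tmin`.
#' @param reference Optional reference `daily_series` (required when runs of
#'   >= 2 consecutive days are missing); see [rank_reference_stations()].
#' @return A list with `series` (imputed copy, `n_imputed` attribute set)
#'   and `log` (data frame `province,date,variable,method,value`; empty when
#'   nothing was missing).
#' @export
impute_temperature <- function(series, reference = NULL) {
  stopifnot(inherits(series, "daily_series"))
  logs <- list()
  for (var in c("tmax", "tmin")) {
    res <- impute_one_var(series, var, reference)
    series[[var]] <- res$values
    if (!is.null(res$log)) logs[[var]] <- res$log
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(province = character(), date = as.Date(character()),
               variable = character(), method = character(),
               value = numeric())
  rownames(log) <- NULL
  attr(series, "n_imputed") <- length(unique(log$date[log$variable == "tmax"]))
  list(series = series, log = log)
}

#' Rank candidate reference stations by correlation
#'
#' Pearson correlation of daily maximum temperature over the days observed
#' in both series, used to pick the most-correlated station for gap
#' imputation.
#'
#' @param series Target `daily_series`.
#' @param candidates List of candidate `daily_series`.
#' @return Data frame `province, correlation, n_overlap`, sorted by
#'   decreasing correlation.
#' @export
rank_reference_stations <- function(series, candidates) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(cand) {
    idx <- match(series$date, cand$date)
    ok <- !is.na(idx) & !is.na(series$tmax) & !is.na(cand$tmax[idx])
    data.frame(province = cand$province[1],
               correlation = if (sum(ok) >= 3)
                 stats::cor(series$tmax[ok], cand$tmax[idx][ok]) else NA_real_,
               n_overlap = sum(ok))
  })
  out <- do.call(rbind, rows)
  out[order(-out$correlation), , drop = FALSE]
}

#' Empirical temperature percentiles for a province
#'
#' Percentiles of the daily maximum temperature over the whole series, using
#' the type-7 convention (linear interpolation of the empirical CDF) —
#' fixed and documented so all downstream knot placement and percentile
#' grids share one convention.
#'
#' @param series A `daily_series`.
#' @param grid Percentiles (0-100) to evaluate; must be supplied sorted or
#'   will be sorted.
#' @return A list of class `temperature_summary`: `province_id`,
#'   `percentiles` (named by percentile), `n_days`, `n_imputed`.
#' @export
temperature_percentiles <- function(series, grid = 0:100) {
  stopifnot(inherits(series, "daily_series"))
  if (nrow(series) == 0L) stopf("empty series")
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid < 0 | grid > 100)) stopf("percentiles must lie in [0, 100]")
  q <- stats::quantile(series$tmax, probs = grid / 100, na.rm = TRUE,
                       type = 7, names = FALSE)
  names(q) <- format(grid, trim = TRUE)
  structure(list(province_id = series$province[1], percentiles = q,
                 n_days = nrow(series),
                 n_imputed = attr(series, "n_imputed") %||% 0L),
            class = "temperature_summary")
}

#' Pooled temperature percentiles across a panel
#'
#' Pools all days of all provinces into one distribution; used for the
#' pooled exposure-response curve and its percentile grid.
#'
#' @param panel List of `daily_series`.
#' @param grid Percentiles (0-100).
#' @return A `temperature_summary` with `province_id = "pooled"`.
#' @export
pooled_temperature_summary <- function(panel, grid = 0:100) {
  tmax <- unlist(lapply(panel, `[[`, "tmax"), use.names = FALSE)
  grid <- sort(unique(as.numeric(grid)))
  q <- stats::quantile(tmax, probs = grid / 100, na.rm = TRUE, type = 7,
                       names = FALSE)
  names(q) <- format(grid, trim = TRUE)
  structure(list(province_id = "pooled", percentiles = q,
                 n_days = length(tmax), n_imputed = 0L),
            class = "temperature_summary")
}

#' Look up the temperature at given percentiles of a summary
#'
#' @param summary A `temperature_summary`.
#' @param percentiles Percentile values present in the summary grid (values
#'   between grid points are linearly interpolated).
#' @return Numeric temperatures (degrees C).
#' @export
summary_temperature <- function(summary, percentiles) {
  stopifnot(inherits(summary, "temperature_summary"))
  grid <- as.numeric(names(summary$percentiles))
  stats::approx(grid, summary$percentiles, xout = percentiles,
                rule = 2, ties = "ordered")$y
}
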
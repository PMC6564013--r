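#' Heat-health prevention plan activation thresholds
#'
#' The plan's province thresholds: 95th percentiles of the historical
#' summer (June-September) daily maximum and minimum temperatures. Official
#' thresholds, where known, can be supplied and are returned verbatim.
#'
#' @param series A `daily_series`.
#' @param summer_months Months considered summer (default June-September).
#' @param tmax_threshold,tmin_threshold Optional supplied official
#'   thresholds (both must be given together).
#' @return A list of class `threshold_pair`: `province_id`,
#'   `tmax_threshold`, `tmin_threshold`, `source`.
#' @export
estimate_thresholds <- function(series, summer_months = 6:9,
                                tmax_threshold = NULL,
                                tmin_threshold = NULL) {
  stopifnot(inherits(series, "daily_series"))
  if (!is.null(tmax_threshold) || !is.null(tmin_threshold)) {
    if (is.null(tmax_threshold) || is.null(tmin_threshold))
      stopf("supply both tmax_threshold and tmin_threshold, or neither")
    return(structure(list(province_id = series$province[1],
                          tmax_threshold = tmax_threshold,
                          tmin_threshold = tmin_threshold,
                          source = "supplied"),
                     class = "threshold_pair"))
  }
  mo <- as.POSIXlt(series$date)$mon + 1L
  summer <- series[mo %in% summer_months, , drop = FALSE]
  if (nrow(summer) == 0) stopf("no summer days in series")
  structure(list(
    province_id = series$province[1],
    tmax_threshold = unname(stats::quantile(summer$tmax, 0.95, type = 7,
                                            na.rm = TRUE)),
    tmin_threshold = unname(stats::quantile(summer$tmin, 0.95, type = 7,
                                            na.rm = TRUE)),
    source = "estimated"),
    class = "threshold_pair")
}

#' Classify daily plan risk levels
#'
#' A day exceeds when its temperatures are above the province thresholds
#' (`rule = "both"` requires both maximum and minimum above their
#' thresholds, matching a plan whose thresholds are set on both; an
#' `"either"` mode is provided since the conjunction is a modelling
#' choice). The risk level of day `t` depends on the number of exceedance
#' days in the window `[t, t+4]` (observed temperatures standing in for
#' forecasts): 0 exceedances give level 0, 1-2 level 1, 3-4 level 2, and 5
#' level 3. Trailing days use the truncated window of available days. The
#' plan counts as activated on days of level 1-3.
#'
#' @param series A `daily_series`.
#' @param thresholds A `threshold_pair`.
#' @param rule `"both"` (default) or `"either"`.
#' @return A list of class `activation_series`: `dates`, `exceedance`,
#'   `level` (0-3), `active` (logical).
#' @export
classify_activation <- function(series, thresholds, rule = c("both", "either")) {
  stopifnot(inherits(series, "daily_series"),
            inherits(thresholds, "threshold_pair"))
  rule <- match.arg(rule)
  if (!is.finite(thresholds$tmax_threshold) ||
      !is.finite(thresholds$tmin_threshold))
    stopf("thresholds must be finite")
  over_max <- series$tmax > thresholds$tmax_threshold
  over_min <- series$tmin > thresholds$tmin_threshold
  exceed <- if (rule == "both") over_max & over_min else over_max | over_min
  exceed[is.na(exceed)] <- FALSE
  n <- length(exceed)
  # forward 5-day window count via reversed cumulative sums
  cs <- cumsum(as.integer(exceed))
  upper <- pmin(seq_len(n) + 4L, n)
  counts <- cs[upper] - c(0L, cs)[seq_len(n)]
  level <- ifelse(counts == 0L, 0L,
                  ifelse(counts <= 2L, 1L, ifelse(counts <= 4L, 2L, 3L)))
  structure(list(dates = series$date, exceedance = exceed,
                 level = as.integer(level), active = level >= 1L,
                 rule = rule),
            class = "activation_series")
}

#' Heat-wave definition
#'
#' A relative-threshold heat-wave definition: at least `min_duration`
#' consecutive days with maximum temperature above the given percentile of
#' the province's historical daily maximum series.
#'
#' @param min_duration Minimum run length (days), typically 2, 3 or 4.
#' @param percentile Threshold percentile, typically 90, 92.5, 95 or 97.5.
#' @return A list of class `heatwave_spec`.
#' @export
heatwave_spec <- function(min_duration = 3L, percentile = 95) {
  if (min_duration < 1) stopf("min_duration must be >= 1")
  if (percentile <= 0 || percentile >= 100)
    stopf("percentile must lie in (0, 100)")
  structure(list(min_duration = as.integer(min_duration),
                 percentile = percentile),
            class = "heatwave_spec")
}

#' Flag heat-wave days
#'
#' Finds maximal runs of consecutive days with `tmax` above the percentile
#' threshold and flags every day inside runs of length at least
#' `min_duration`.
#'
#' @param series A `daily_series`.
#' @param spec A `heatwave_spec`.
#' @param summary Optional `temperature_summary` supplying the percentile
#'   (computed from the series when omitted).
#' @return A list of class `heatwave_flags`: `indicator` (0/1 per day),
#'   `waves` (data frame `start, end, length`), `threshold`.
#' @export
flag_heatwaves <- function(series, spec, summary = NULL) {
  stopifnot(inherits(series, "daily_series"), inherits(spec, "heatwave_spec"))
  threshold <- if (is.null(summary)) {
    unname(stats::quantile(series$tmax, spec$percentile / 100, type = 7,
                           na.rm = TRUE))
  } else {
    summary_temperature(summary, spec$percentile)
  }
  over <- series$tmax > threshold
  over[is.na(over)] <- FALSE
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hot <- which(r$values)
  qualifying <- hot[r$lengths[hot] >= spec$min_duration]
  indicator <- integer(length(over))
  waves <- data.frame(start = as.Date(character()),
                      end = as.Date(character()), length = integer())
  if (length(qualifying)) {
    for (q in qualifying) indicator[starts[q]:ends[q]] <- 1L
    waves <- data.frame(start = series$date[starts[qualifying]],
                        end = series$date[ends[qualifying]],
                        length = r$lengths[qualifying])
  }
  structure(list(indicator = indicator, waves = waves,
                 threshold = threshold, spec = spec),
            class = "heatwave_flags")
}

#' Summer indicator regression for one province
#'
#' Quasi-Poisson regression of daily counts on a binary indicator (plan
#' activation or heat-wave day), restricted to the summer window (June 1 to
#' September 15 by default), replacing the temperature cross-basis.
#' Confounders: weekday, holiday, optionally influenza, a 3-df natural
#' cubic spline of day-of-season per calendar year, and a linear year term.
#' A constant indicator within the window yields a non-converged flag
#' rather than an error.
#'
#' @param series A `daily_series`.
#' @param indicator 0/1 vector aligned with `series` rows (full series;
#'   the function subsets to the window).
#' @param window Character month-day pair `c("06-01", "09-15")`.
#' @param seasonality_df Seasonal df per summer (default 3).
#' @param adjust_influenza Include the influenza covariate.
#' @return A list of class `indicator_effect`: `province_id`, `log_rr`,
#'   `se`, `converged`, `reason`, `n_days`, `n_active`.
#' @export
fit_indicator_model <- function(series, indicator,
                                window = c("06-01", "09-15"),
                                seasonality_df = 3L,
                                adjust_influenza = TRUE) {
  stopifnot(inherits(series, "daily_series"),
            length(indicator) == nrow(series))
  md <- format(series$date, "%m-%d")
  in_window <- md >= window[1] & md <= window[2]
  sub <- series[in_window, , drop = FALSE]
  ind <- as.numeric(indicator[in_window])
  out <- function(converged, log_rr = NA_real_, se = NA_real_, reason = NULL)
    structure(list(province_id = series$province[1], log_rr = log_rr,
                   se = se, converged = converged, reason = reason,
                   n_days = nrow(sub), n_active = sum(ind > 0)),
              class = "indicator_effect")
  if (nrow(sub) == 0) return(out(FALSE, reason = "empty summer window"))
  if (length(unique(ind)) < 2)
    return(out(FALSE, reason = "indicator constant within window"))

  dos <- as.numeric(sub$date - as.Date(paste0(format(sub$date, "%Y-"),
                                              window[1])))
  yr <- year_of(sub$date)
  years <- sort(unique(yr))
  dk <- seq(min(dos), max(dos), length.out = seasonality_df + 1L)
  seas_spec <- basis_spec("natural-cubic",
                          internal_knots = dk[2:seasonality_df],
                          boundary = range(dos), intercept = FALSE)
  S1 <- eval_basis(dos, seas_spec)
  seas <- matrix(0, nrow(sub), seasonality_df * length(years))
  for (k in seq_along(years)) {
    idx <- (k - 1L) * seasonality_df + seq_len(seasonality_df)
    seas[, idx] <- S1 * (yr == years[k])
  }
  colnames(seas) <- sprintf("seas%d.y%d",
                            rep(seq_len(seasonality_df), length(years)),
                            rep(years, each = seasonality_df))
  dow <- matrix(0, nrow(sub), 6, dimnames = list(NULL, paste0("dow", 1:6)))
  for (d in 1:6) dow[, d] <- as.numeric(sub$dow == d)
  X <- cbind(`(Intercept)` = 1, indicator = ind, dow,
             holiday = as.numeric(sub$holiday))
  if (adjust_influenza) X <- cbind(X, influenza = as.numeric(sub$influenza))
  X <- cbind(X, seas,
             year = (yr - mean(yr)))
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2,
                        function(col) stats::sd(col) > 0))
  X <- X[, keep, drop = FALSE]
  fit <- fit_quasipoisson(sub$count, X)
  i_idx <- match("indicator", colnames(X))
  if (!fit$converged || is.na(fit$coef[i_idx]) ||
      !is.finite(fit$vcov[i_idx, i_idx]))
    return(out(FALSE, reason = fit$reason %||% "unstable fit"))
  out(TRUE, log_rr = unname(fit$coef[i_idx]),
      se = sqrt(fit$vcov[i_idx, i_idx]))
}

#' Univariate random-effects meta-analysis of indicator effects
#'
#' Pools the converged province-specific indicator log relative risks with
#' a standard univariate random-effects model (REML or DerSimonian-Laird,
#' via `metafor::rma.uni`) and reports the pooled effect as a percent
#' change. Confidence intervals use the modified (truncated)
#' Knapp-Hartung adjustment: the pooled standard error is scaled by the
#' observed between-province scatter but never below the conventional
#' inverse-variance value, with a t reference on n - 1 df - the
#' recommended interval for random-effects pooling of a moderate number
#' of provinces.
#'
#' @param effects List of `indicator_effect`s.
#' @param method `"reml"` or `"dl"`.
#' @return A list of class `pooled_indicator_effect`: `percent_change`,
#'   `ci_low`, `ci_high`, `log_rr`, `se`, `tau2`, `n_provinces`,
#'   `n_excluded`.
#' @export
univariate_meta <- function(effects, method = c("reml", "dl")) {
  method <- match.arg(method)
  ok <- vapply(effects, function(e) isTRUE(e$converged), logical(1))
  if (!any(ok)) stopf("no converged indicator effects to pool")
  yi <- vapply(effects[ok], `[[`, numeric(1), "log_rr")
  sei <- vapply(effects[ok], `[[`, numeric(1), "se")
  if (sum(ok) == 1L) {
    b <- yi; se <- sei; tau2 <- 0
    z <- stats::qnorm(0.975)
    lo <- b - z * se; hi <- b + z * se
  } else {
    fit <- metafor::rma.uni(yi = yi, sei = sei, method = toupper(method),
                            test = "knha")
    b <- as.numeric(fit$beta); tau2 <- fit$tau2
    se_z <- sqrt(1 / sum(1 / (sei^2 + tau2)))
    se <- max(fit$se, se_z)
    tq <- stats::qt(0.975, sum(ok) - 1)
    lo <- b - tq * se; hi <- b + tq * se
  }
  structure(list(percent_change = 100 * (exp(b) - 1),
                 ci_low = 100 * (exp(lo) - 1),
                 ci_high = 100 * (exp(hi) - 1),
                 log_rr = b, se = se, tau2 = tau2,
                 n_provinces = sum(ok), n_excluded = sum(!ok)),
            class = "pooled_indicator_effect")
}
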
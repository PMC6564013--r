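#' Simulation configuration
#'
#' Bundles every knob of the multi-province synthetic registry emulator.
#' Defaults reproduce the study conditions of the Spanish hospital-admission
#' setting the package targets: 50 provinces observed daily over 1997-2013,
#' province mean maximum temperatures spanning roughly 17-26 degrees C, an
#' annual temperature cycle peaking in mid-July, first-order autocorrelated
#' weather noise, weekday/holiday/seasonally structured admission counts with
#' quasi-Poisson overdispersion, and a winter-pulsed influenza series.
#'
#' @param n_provinces Number of provinces (>= 1).
#' @param years Contiguous calendar years to simulate.
#' @param baseline_rate Expected admissions/day per province at reference
#'   conditions.
#' @param seasonal_amplitude Log-scale amplitude of the annual admission
#'   cycle (peak mid-January).
#' @param dow_effects Seven log-scale weekday offsets (Sunday first).
#' @param holiday_effect Log-scale offset on public holidays.
#' @param temp_mean Province mean of daily maximum temperature (degrees C);
#'   used when `temp_province_range` is `NULL` or a single province is drawn.
#' @param temp_annual_amplitude Amplitude (degrees C) of the annual sinusoid.
#' @param temp_ar1 AR(1) coefficient of daily temperature noise, in \[0, 1).
#' @param temp_sd Marginal standard deviation (degrees C) of the temperature
#'   noise; must be non-negative (zero gives the deterministic sinusoid).
#' @param diurnal_range,diurnal_sd Mean and SD of the daily tmax - tmin range.
#' @param temp_province_range Length-2 range of province mean temperatures;
#'   province means are equally spaced across it (set `NULL` to use
#'   `temp_mean` for every province).
#' @param influenza_rate,influenza_amplitude Baseline rate and log-scale
#'   winter amplitude of the influenza admission series.
#' @param dispersion Quasi-Poisson variance inflation (>= 1); counts are
#'   negative-binomial with variance `dispersion * mu`.
#' @param curve_heterogeneity_sd SD of the multiplicative between-province
#'   scaling of the true exposure-response curve (0 = identical provinces).
#' @param lead_in If `TRUE`, 21 lead-in days are simulated before the first
#'   year so that no day needs truncated lag weights; the lead-in days are
#'   dropped from the returned panel.
#' @param seed Master integer seed; all sub-streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_provinces = 50L,
                       years = 1997:2013,
                       baseline_rate = 15,
                       seasonal_amplitude = 0.15,
                       dow_effects = c(-0.10, 0.06, 0.05, 0.04, 0.03, 0.02, -0.16),
                       holiday_effect = -0.2,
                       temp_mean = 21,
                       temp_annual_amplitude = 8,
                       temp_ar1 = 0.7,
                       temp_sd = 2.5,
                       diurnal_range = 10,
                       diurnal_sd = 1.5,
                       temp_province_range = c(17, 26),
                       influenza_rate = 0.5,
                       influenza_amplitude = 2,
                       dispersion = 1.5,
                       curve_heterogeneity_sd = 0.10,
                       lead_in = FALSE,
                       seed = 1L) {
  if (n_provinces < 1) stopf("invalid config: n_provinces must be >= 1")
  if (length(years) == 0) stopf("invalid config: years must be non-empty")
  if (any(diff(sort(years)) != 1))
    stopf("invalid config: years must be contiguous")
  if (dispersion < 1) stopf("invalid config: dispersion must be >= 1")
  if (temp_ar1 < 0 || temp_ar1 >= 1)
    stopf("invalid config: temp_ar1 must lie in [0, 1)")
  if (temp_sd < 0) stopf("invalid config: temp_sd must be non-negative")
  if (length(dow_effects) != 7)
    stopf("invalid config: dow_effects must have length 7")
  structure(list(
    n_provinces = as.integer(n_provinces), years = as.integer(sort(years)),
    baseline_rate = baseline_rate, seasonal_amplitude = seasonal_amplitude,
    dow_effects = dow_effects, holiday_effect = holiday_effect,
    temp_mean = temp_mean, temp_annual_amplitude = temp_annual_amplitude,
    temp_ar1 = temp_ar1, temp_sd = temp_sd,
    diurnal_range = diurnal_range, diurnal_sd = diurnal_sd,
    temp_province_range = temp_province_range,
    influenza_rate = influenza_rate,
    influenza_amplitude = influenza_amplitude,
    dispersion = dispersion,
    curve_heterogeneity_sd = curve_heterogeneity_sd,
    lead_in = isTRUE(lead_in), seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed national holidays used by the generator (month * 100 + day).
.holiday_md <- c(101, 106, 501, 815, 1012, 1101, 1206, 1208, 1225)

holiday_flag <- function(dates) {
  lt <- as.POSIXlt(dates)
  as.integer(((lt$mon + 1L) * 100L + lt$mday) %in% .holiday_md)
}

#' True exposure-lag-response association
#'
#' The ground truth recoverable by the pipeline: a cumulative
#' exposure-response curve in log-relative-risk units anchored at 0 at its
#' reference temperature, distributed over lags 0..21 by a non-negative
#' weight vector summing to one.
#'
#' @param curve Function mapping temperature (degrees C) to cumulative
#'   log relative risk; must satisfy `curve(reference_temp) == 0`.
#' @param lag_weights Length-22 non-negative weights over lags 0..21 summing
#'   to 1 (within 1e-12).
#' @param reference_temp Temperature (degrees C) at which the cumulative
#'   log-RR is zero.
#' @return A list of class `true_association`.
#' @export
true_association <- function(curve, lag_weights = decaying_lag_weights(),
                             reference_temp = 20) {
  stopifnot(is.function(curve))
  if (length(lag_weights) != 22L)
    stopf("lag_weights must have length 22 (lags 0..21)")
  if (any(lag_weights < 0)) stopf("lag_weights must be non-negative")
  if (abs(sum(lag_weights) - 1) > 1e-12)
    stopf("lag_weights must sum to 1 (got %.15f)", sum(lag_weights))
  if (abs(curve(reference_temp)) > 1e-6)
    stopf("curve(reference_temp) must be 0 (got %.3g)", curve(reference_temp))
  structure(list(curve = curve, lag_weights = lag_weights,
                 reference_temp = reference_temp),
            class = "true_association")
}

#' Smoothly decaying lag weights
#'
#' Default true lag structure: weights proportional to `exp(-lag / scale)`
#' over lags 0..21, normalized to sum to one. Mimics temperature effects that
#' are strongest immediately and decay over about three weeks.
#'
#' @param scale Exponential decay scale in days.
#' @return Length-22 numeric vector summing to 1.
#' @export
decaying_lag_weights <- function(scale = 5) {
  w <- exp(-(0:21) / scale)
  w / sum(w)
}

#' Null association (no temperature effect)
#'
#' @return A `true_association` whose curve is identically zero.
#' @export
null_truth <- function() {
  true_association(function(x) rep(0, length(x)),
                   lag_weights = rep(1 / 22, 22), reference_temp = 20)
}

#' Percentile-anchored V-shaped truth factory
#'
#' Builds, for each province, a true cumulative exposure-response curve
#' defined on that province's own temperature percentile scale: a smooth
#' (C1, piecewise-quadratic) V with value `log(1 + cold_pct/100)` at the 1st
#' percentile, minimum 0 at `min_percentile`, and `log(1 + heat_pct/100)` at
#' the 99th percentile. Anchoring on percentiles makes the pooled
#' (percentile-aligned) second-stage estimand identical across provinces
#' with different climates.
#'
#' @param cold_pct True percent change at the 1st temperature percentile.
#' @param heat_pct True percent change at the 99th percentile.
#' @param min_percentile Percentile of minimum risk (the true MHP).
#' @param lag_weights Length-22 lag weight vector (see
#'   [decaying_lag_weights()]).
#' @return A function of class `truth_factory`: given a
#'   `temperature_summary` for a province it returns that province's
#'   `true_association`.
#' @export
percentile_truth <- function(cold_pct = 35, heat_pct = 14,
                             min_percentile = 75,
                             lag_weights = decaying_lag_weights()) {
  lc <- log1p(cold_pct / 100)
  lh <- log1p(heat_pct / 100)
  pm <- min_percentile
  g <- function(p) {
    ifelse(p <= pm,
           lc * ((pm - p) / (pm - 1))^2,
           lh * ((p - pm) / (99 - pm))^2)
  }
  factory <- function(summary) {
    stopifnot(inherits(summary, "temperature_summary"))
    pcts <- summary$percentiles
    grid_p <- as.numeric(names(pcts))
    # piecewise-linear percentile lookup from the empirical quantiles
    to_pct <- function(temp) {
      stats::approx(x = pcts, y = grid_p, xout = temp, rule = 2,
                    ties = "ordered")$y
    }
    ref_temp <- unname(stats::approx(x = grid_p, y = pcts, xout = pm,
                                     rule = 2, ties = "ordered")$y)
    curve <- function(temp) g(to_pct(temp))
    true_association(curve, lag_weights = lag_weights,
                     reference_temp = ref_temp)
  }
  class(factory) <- c("truth_factory", "function")
  attr(factory, "cold_pct") <- cold_pct
  attr(factory, "heat_pct") <- heat_pct
  attr(factory, "min_percentile") <- min_percentile
  factory
}

province_means <- function(config) {
  rng <- config$temp_province_range
  if (is.null(rng) || config$n_provinces == 1L)
    rep(config$temp_mean, config$n_provinces)
  else seq(rng[1], rng[2], length.out = config$n_provinces)
}

sim_dates <- function(config) {
  from <- as.Date(sprintf("%d-01-01", min(config$years)))
  to <- as.Date(sprintf("%d-12-31", max(config$years)))
  if (config$lead_in) from <- from - 21L
  seq(from, to, by = "day")
}

#' Simulate one province's daily temperature series
#'
#' Daily maximum temperature is a province-specific mean plus an annual
#' sinusoid peaking on day-of-year 196 (mid-July) plus stationary AR(1)
#' Gaussian noise with marginal SD `temp_sd`; the minimum is the maximum
#' minus a positive stochastic diurnal range. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param province_index Which province (1-based), sets the mean level.
#' @param seed Seed for this series (defaults to a sub-seed of
#'   `config$seed`).
#' @return A `daily_series` with temperatures, holiday flags and weekday
#'   indices; counts and influenza are `NA`/0 until [generate_counts()].
#' @export
generate_temperature <- function(config, province_index = 1L,
                                 seed = sub_seed(config$seed,
                                                 province_index, 1L)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$temp_sd < 0) stopf("invalid config: temp_sd must be non-negative")
  if (province_index < 1 || province_index > config$n_provinces)
    stopf("province_index out of range 1..%d", config$n_provinces)
  dates <- sim_dates(config)
  n <- length(dates)
  doy <- day_of_year(dates)
  mean_p <- province_means(config)[province_index]
  det <- mean_p + config$temp_annual_amplitude *
    cos(2 * pi * (doy - 196) / 365.25)
  with_seed(seed, {
    if (config$temp_sd > 0) {
      innov_sd <- config$temp_sd * sqrt(1 - config$temp_ar1^2)
      eps <- stats::rnorm(n, 0, innov_sd)
      noise <- as.numeric(stats::filter(eps, config$temp_ar1,
                                        method = "recursive"))
    } else noise <- numeric(n)
    drange <- pmax(0.5, stats::rnorm(n, config$diurnal_range,
                                     config$diurnal_sd))
    tmax <- det + noise
    daily_series(province = sprintf("P%02d", province_index),
                 dates = dates, tmax = tmax, tmin = tmax - drange,
                 holiday = holiday_flag(dates))
  })
}

# Lag-weighted cumulative curve signal with truncated/renormalized weights
# for the first 21 days (no lag history yet).
lagged_signal <- function(curve_vals, lag_weights) {
  n <- length(curve_vals)
  s <- if (n >= length(lag_weights))
    as.numeric(stats::filter(curve_vals, lag_weights, sides = 1))
  else rep(NA_real_, n)
  head_n <- min(21L, n)
  for (t in seq_len(head_n)) {
    w <- lag_weights[seq_len(t)]
    s[t] <- sum(w * curve_vals[t:1]) / sum(w)
  }
  s
}

#' Simulate admission counts for one province
#'
#' Expected counts follow a log-linear model: log baseline + annual seasonal
#' cycle + weekday effect + holiday effect + the lag-weighted true
#' cumulative temperature curve. The first 21 days use truncated,
#' renormalized lag weights. Counts are negative-binomial parameterized to
#' match the quasi-Poisson mean-variance law `Var = dispersion * mu`
#' (Poisson when `dispersion == 1`). An independent winter-pulsed Poisson
#' influenza series is attached so the regression's influenza adjustment is
#' exercised.
#'
#' @param temps A `daily_series` with temperatures (from
#'   [generate_temperature()]).
#' @param truth A [true_association()].
#' @param config A [sim_config()].
#' @param seed Seed for the count draws.
#' @param extra_log_rate Optional numeric vector (length `nrow(temps)`)
#'   added to the linear predictor, e.g. to inject an indicator effect.
#' @return The `daily_series` with `count` and `influenza` filled in; the
#'   deterministic expected counts are attached as attribute `"mu"`.
#' @export
generate_counts <- function(temps, truth, config,
                            seed = sub_seed(config$seed, 1L, 2L),
                            extra_log_rate = NULL) {
  stopifnot(inherits(temps, "daily_series"),
            inherits(truth, "true_association"),
            inherits(config, "sim_config"))
  if (config$dispersion < 1) stopf("invalid config: dispersion must be >= 1")
  cv <- truth$curve(temps$tmax)
  if (any(!is.finite(cv)))
    stopf("truth curve is not defined on the realized temperature range")
  s <- lagged_signal(cv, truth$lag_weights)
  doy <- day_of_year(temps$date)
  eta <- log(config$baseline_rate) +
    config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    config$dow_effects[temps$dow + 1L] +
    config$holiday_effect * temps$holiday +
    s
  if (!is.null(extra_log_rate)) {
    stopifnot(length(extra_log_rate) == nrow(temps))
    eta <- eta + extra_log_rate
  }
  mu <- exp(eta)
  out <- with_seed(seed, {
    counts <- if (config$dispersion == 1) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu,
                        size = mu / (config$dispersion - 1))
    flu_mu <- config$influenza_rate *
      exp(config$influenza_amplitude * cos(2 * pi * (doy - 25) / 365.25))
    flu <- stats::rpois(length(mu), flu_mu)
    temps$count <- as.integer(counts)
    temps$influenza <- as.integer(flu)
    temps
  })
  attr(out, "mu") <- mu
  validate_daily_series(out)
  out
}

#' Simulate a multi-province daily panel
#'
#' One `daily_series` per province, with distinct deterministic sub-seeds
#' and province mean temperatures spaced across
#' `config$temp_province_range`. When `truth` is a factory (see
#' [percentile_truth()]) the per-province curve is anchored on the
#' province's realized temperature percentiles; a multiplicative
#' between-province scaling with SD `config$curve_heterogeneity_sd` is then
#' applied so provinces genuinely differ.
#'
#' @param config A [sim_config()].
#' @param truth A [true_association()], a `truth_factory`, or a list with
#'   one `true_association` per province.
#' @return A named list of `daily_series` (class `panel`).
#' @export
generate_panel <- function(config, truth = percentile_truth()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_provinces < 1) stopf("invalid config: n_provinces must be >= 1")
  temps <- lapply(seq_len(config$n_provinces), function(i)
    generate_temperature(config, i))
  truths <- resolve_truths(truth, temps, config)
  panel <- lapply(seq_len(config$n_provinces), function(i) {
    ds <- generate_counts(temps[[i]], truths[[i]], config,
                          seed = sub_seed(config$seed, i, 2L))
    if (config$lead_in) {
      mu <- attr(ds, "mu")
      keep <- ds$date >= as.Date(sprintf("%d-01-01", min(config$years)))
      ds <- ds[keep, , drop = FALSE]
      class(ds) <- c("daily_series", "data.frame")
      attr(ds, "mu") <- mu[keep]
    }
    ds
  })
  names(panel) <- vapply(panel, function(d) d$province[1], character(1))
  structure(panel, class = c("panel", "list"), truths = truths)
}

resolve_truths <- function(truth, temps, config) {
  n <- length(temps)
  truths <- if (inherits(truth, "truth_factory")) {
    lapply(temps, function(ds)
      truth(temperature_percentiles(ds, grid = 0:100)))
  } else if (inherits(truth, "true_association")) {
    rep(list(truth), n)
  } else if (is.list(truth) && length(truth) == n) {
    truth
  } else stopf("truth must be a true_association, truth_factory, or list")
  if (config$curve_heterogeneity_sd > 0) {
    scales <- with_seed(sub_seed(config$seed, 0L, 3L),
                        1 + stats::rnorm(n, 0, config$curve_heterogeneity_sd))
    truths <- lapply(seq_len(n), function(i) {
      tr <- truths[[i]]
      sc <- scales[i]
      base_curve <- tr$curve
      true_association(function(x) sc * base_curve(x),
                       lag_weights = tr$lag_weights,
                       reference_temp = tr$reference_temp)
    })
  }
  truths
}
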
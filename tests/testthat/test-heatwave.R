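make_threshold <- function(tmax = 30, tmin = 18) {
  structure(list(province_id = "PX", tmax_threshold = tmax,
                 tmin_threshold = tmin, source = "estimated"),
            class = "threshold_pair")
}

# brute-force oracle for the 5-day forward window level rule
level_oracle <- function(exceed) {
  n <- length(exceed)
  vapply(seq_len(n), function(t) {
    cnt <- sum(exceed[t:min(t + 4, n)])
    if (cnt == 0) 0L else if (cnt <= 2) 1L else if (cnt <= 4) 2L else 3L
  }, integer(1))
}

test_that("thresholds are the 95th percentiles of summer temperatures only", {
  p <- generate_panel(quick_config(n_provinces = 1, years = 2000:2004),
                      null_truth())
  ds <- p[[1]]
  mo <- as.POSIXlt(ds$date)$mon + 1
  thr <- estimate_thresholds(ds)
  expect_equal(thr$tmax_threshold,
               unname(quantile(ds$tmax[mo %in% 6:9], 0.95, type = 7)))
  expect_equal(thr$source, "estimated")
  expect_lte(thr$tmin_threshold, thr$tmax_threshold)

  # a scorching winter day must not move the summer thresholds
  ds2 <- ds
  jan <- which(mo == 1)[1]
  ds2$tmax[jan] <- 50
  ds2$tmin[jan] <- 40
  thr2 <- estimate_thresholds(ds2)
  expect_equal(thr2$tmax_threshold, thr$tmax_threshold)
  expect_equal(thr2$tmin_threshold, thr$tmin_threshold)
})

test_that("constant summer temperatures give that constant as threshold", {
  ds <- daily_series("PX", as.Date("2001-06-01") + 0:119,
                     tmax = rep(30, 120), tmin = rep(18, 120), count = 1L)
  thr <- estimate_thresholds(ds)
  expect_equal(thr$tmax_threshold, 30)
  expect_equal(thr$tmin_threshold, 18)
})

test_that("supplied official thresholds are returned verbatim", {
  ds <- constant_series(n = 30)
  thr <- estimate_thresholds(ds, tmax_threshold = 32, tmin_threshold = 20)
  expect_equal(thr$tmax_threshold, 32)
  expect_equal(thr$tmin_threshold, 20)
  expect_equal(thr$source, "supplied")
})

test_that("all 32 five-day exceedance patterns map to the level rule", {
  thr <- make_threshold()
  for (bits in 0:31) {
    e <- as.integer(intToBits(bits))[1:5]
    ds <- daily_series("PX", as.Date("2001-07-01") + 0:4,
                       tmax = ifelse(e == 1, 31, 25),
                       tmin = ifelse(e == 1, 19, 15), count = 1L)
    act <- classify_activation(ds, thr)
    expect_equal(act$level[1], c(0L, 1L, 1L, 2L, 2L, 3L)[sum(e) + 1])
    expect_equal(act$active, act$level >= 1)
  }
})

test_that("activation levels equal the brute-force window oracle", {
  set.seed(55)
  n <- 1000
  ds <- daily_series("PX", as.Date("2001-01-01") + 0:(n - 1),
                     tmax = runif(n, 20, 40), tmin = runif(n, 10, 20),
                     count = 1L)
  thr <- make_threshold(34, 17)
  act <- classify_activation(ds, thr)
  exceed <- ds$tmax > 34 & ds$tmin > 17
  expect_equal(act$level, level_oracle(exceed))
  expect_equal(act$exceedance, exceed)
  # no exceedances -> all level 0
  act0 <- classify_activation(ds, make_threshold(100, 100))
  expect_true(all(act0$level == 0) && !any(act0$active))
})

test_that("raising one day's temperatures never lowers any level", {
  set.seed(56)
  n <- 200
  ds <- daily_series("PX", as.Date("2001-01-01") + 0:(n - 1),
                     tmax = runif(n, 20, 40), tmin = runif(n, 10, 20),
                     count = 1L)
  thr <- make_threshold(34, 17)
  base <- classify_activation(ds, thr)$level
  for (d in c(3, 50, 120)) {
    ds2 <- ds
    ds2$tmax[d] <- 45
    ds2$tmin[d] <- 25
    expect_true(all(classify_activation(ds2, thr)$level >= base))
  }
})

test_that("either-rule activation is at least as frequent as both-rule", {
  set.seed(57)
  n <- 300
  ds <- daily_series("PX", as.Date("2001-01-01") + 0:(n - 1),
                     tmax = runif(n, 20, 40), tmin = runif(n, 10, 20),
                     count = 1L)
  thr <- make_threshold(34, 17)
  both <- classify_activation(ds, thr, rule = "both")
  either <- classify_activation(ds, thr, rule = "either")
  expect_true(all(either$level >= both$level))
})

test_that("heat-wave run detection matches the stated patterns", {
  mk <- function(pattern) {
    daily_series("PX", as.Date("2001-07-01") + seq_along(pattern) - 1,
                 tmax = ifelse(pattern == 1, 36, 25),
                 tmin = ifelse(pattern == 1, 20, 14), count = 1L)
  }
  sm <- structure(list(province_id = "PX",
                       percentiles = c("0" = 10, "95" = 30, "100" = 50),
                       n_days = 6L, n_imputed = 0L),
                  class = "temperature_summary")
  ds <- mk(c(1, 1, 0, 1, 1, 1))
  hw <- flag_heatwaves(ds, heatwave_spec(3, 95), sm)
  expect_equal(hw$indicator, c(0, 0, 0, 1, 1, 1))
  expect_equal(hw$waves$length, 3L)

  hw2 <- flag_heatwaves(mk(c(1, 0, 1, 0)), heatwave_spec(2, 95), sm)
  expect_true(all(hw2$indicator == 0))
})

test_that("heat-wave flags equal a brute-force run scan on random series", {
  brute <- function(over, dmin) {
    # day-by-day scan: a day is flagged iff it belongs to some window of
    # dmin consecutive over-threshold days
    n <- length(over)
    ind <- integer(n)
    for (s in seq_len(n - dmin + 1)) {
      if (all(over[s:(s + dmin - 1)]))
        ind[s:(s + dmin - 1)] <- 1L
    }
    ind
  }
  set.seed(58)
  for (r in 1:20) {
    n <- 400
    ds <- daily_series("PX", as.Date("2001-01-01") + 0:(n - 1),
                       tmax = runif(n, 20, 40), tmin = runif(n, 10, 19),
                       count = 1L)
    sm <- temperature_percentiles(ds, c(0, 50, 90, 92.5, 95, 97.5, 100))
    for (dmin in 2:4) {
      spec <- heatwave_spec(dmin, 95)
      hw <- flag_heatwaves(ds, spec, sm)
      over <- ds$tmax > summary_temperature(sm, 95)
      expect_equal(hw$indicator, brute(over, dmin))
    }
  }
})

test_that("flagged days are monotone in percentile and nested in duration", {
  set.seed(59)
  n <- 600
  ds <- daily_series("PX", as.Date("2001-01-01") + 0:(n - 1),
                     tmax = runif(n, 20, 40), tmin = runif(n, 10, 19),
                     count = 1L)
  sm <- temperature_percentiles(ds, c(0, 90, 92.5, 95, 97.5, 100))
  flags <- function(d, p) flag_heatwaves(ds, heatwave_spec(d, p), sm)$indicator
  for (d in 2:4) {
    f90 <- flags(d, 90); f95 <- flags(d, 95); f975 <- flags(d, 97.5)
    expect_lte(sum(f95), sum(f90))
    expect_lte(sum(f975), sum(f95))
  }
  for (p in c(90, 95)) {
    f2 <- flags(2, p); f3 <- flags(3, p); f4 <- flags(4, p)
    # every day of a (d+1)-wave is a d-wave day
    expect_true(all(f3 <= f2))
    expect_true(all(f4 <= f3))
  }
})

test_that("constant indicator within the window flags non-convergence", {
  p <- generate_panel(quick_config(n_provinces = 1, years = 2000:2002),
                      null_truth())
  eff <- fit_indicator_model(p[[1]], rep(0L, nrow(p[[1]])))
  expect_false(eff$converged)
  expect_match(eff$reason, "constant")
  expect_error(univariate_meta(list(eff)), "no converged")
})

test_that("a known indicator effect is recovered by the summer model", {
  cfg <- sim_config(n_provinces = 1, years = 2000:2005, baseline_rate = 25,
                    dispersion = 1.2, curve_heterogeneity_sd = 0,
                    temp_province_range = NULL, seed = 61)
  temps <- generate_temperature(cfg, 1)
  thr <- estimate_thresholds(temps)
  act <- classify_activation(temps, thr)
  ds <- generate_counts(temps, null_truth(), cfg,
                        extra_log_rate = log(1.2) * act$active)
  eff <- fit_indicator_model(ds, as.integer(act$active))
  expect_true(eff$converged)
  expect_lt(abs(eff$log_rr - log(1.2)), 3 * eff$se)
})

test_that("univariate pooling: identity, homogeneity, tau2 recovery", {
  mk_eff <- function(b, se, id = "P01")
    structure(list(province_id = id, log_rr = b, se = se, converged = TRUE,
                   reason = NULL, n_days = 500, n_active = 40),
              class = "indicator_effect")
  one <- univariate_meta(list(mk_eff(log(1.05), 0.02)))
  expect_equal(one$log_rr, log(1.05))
  expect_equal(one$percent_change, 5, tolerance = 1e-10)

  same <- univariate_meta(lapply(1:8, function(i)
    mk_eff(0.04, 0.03, sprintf("P%02d", i))))
  expect_equal(same$log_rr, 0.04, tolerance = 1e-8)
  expect_lt(same$tau2, 1e-8)

  set.seed(62)
  tau <- 0.05
  effs <- lapply(1:100, function(i)
    mk_eff(rnorm(1, 0.05, sqrt(tau^2 + 0.03^2)), 0.03, sprintf("P%03d", i)))
  het <- univariate_meta(effs)
  expect_lt(abs(sqrt(het$tau2) - tau) / tau, 0.5)
})
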
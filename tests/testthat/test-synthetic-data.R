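strip_attrs <- function(panel) {
  lapply(panel, function(d) {
    attributes(d) <- attributes(d)[c("names", "row.names", "class")]
    d
  })
}

test_that("noise-free temperatures are exactly the annual sinusoid", {
  cfg <- quick_config(n_provinces = 1, temp_ar1 = 0, temp_sd = 0,
                      temp_province_range = NULL)
  ds <- generate_temperature(cfg, 1)
  doy <- as.POSIXlt(ds$date)$yday + 1
  expected <- cfg$temp_mean +
    cfg$temp_annual_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  expect_equal(ds$tmax, expected)
  expect_equal(generate_temperature(cfg, 1)$tmax, ds$tmax)
  # peak lands in mid-July
  expect_equal(format(ds$date[which.max(ds$tmax)], "%m"), "07")
})

test_that("zero amplitude and zero noise give constant temperature", {
  cfg <- quick_config(n_provinces = 1, temp_annual_amplitude = 0,
                      temp_ar1 = 0, temp_sd = 0, temp_province_range = NULL)
  expect_equal(unique(generate_temperature(cfg, 1)$tmax), cfg$temp_mean)
})

test_that("generators are bit-reproducible per seed and change with it", {
  cfg <- quick_config(seed = 4)
  p1 <- generate_panel(cfg, null_truth())
  p2 <- generate_panel(cfg, null_truth())
  expect_identical(strip_attrs(p1), strip_attrs(p2))
  p3 <- generate_panel(quick_config(seed = 5), null_truth())
  expect_false(identical(strip_attrs(p1), strip_attrs(p3)))
})

test_that("invalid configurations error", {
  expect_error(sim_config(dispersion = 0.5), "dispersion")
  expect_error(sim_config(temp_ar1 = 1), "temp_ar1")
  expect_error(sim_config(temp_sd = -1), "temp_sd")
  expect_error(sim_config(n_provinces = 0), "n_provinces")
  expect_error(sim_config(years = c(2000, 2002)), "contiguous")
})

test_that("null truth with no covariate effects gives Poisson(baseline)", {
  cfg <- sim_config(n_provinces = 1, years = 1990:2017, baseline_rate = 10,
                    seasonal_amplitude = 0, dow_effects = rep(0, 7),
                    holiday_effect = 0, dispersion = 1,
                    curve_heterogeneity_sd = 0, temp_province_range = NULL,
                    seed = 2)
  ds <- generate_panel(cfg, null_truth())[[1]]
  n <- nrow(ds)
  expect_gt(n, 1e4)
  se <- sqrt(cfg$baseline_rate / n)
  expect_lt(abs(mean(ds$count) - cfg$baseline_rate), 3 * se)
  # variance/mean ratio near 1 for Poisson
  expect_lt(abs(var(ds$count) / mean(ds$count) - 1), 0.1)
})

test_that("dispersion 4 yields a Pearson variance/mean ratio near 4", {
  cfg <- sim_config(n_provinces = 1, years = 1990:2017, baseline_rate = 10,
                    seasonal_amplitude = 0, dow_effects = rep(0, 7),
                    holiday_effect = 0, dispersion = 4,
                    curve_heterogeneity_sd = 0, temp_province_range = NULL,
                    seed = 3)
  ds <- generate_panel(cfg, null_truth())[[1]]
  ratio <- var(ds$count) / mean(ds$count)
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("a lag-0 step truth doubles the expected count above threshold", {
  cfg <- sim_config(n_provinces = 1, years = 2000:2002, baseline_rate = 20,
                    seasonal_amplitude = 0, dow_effects = rep(0, 7),
                    holiday_effect = 0, dispersion = 1,
                    curve_heterogeneity_sd = 0, temp_province_range = NULL,
                    seed = 4)
  temps <- generate_temperature(cfg, 1)
  ds <- generate_counts(temps, step_truth(20), cfg)
  mu <- attr(ds, "mu")
  after <- 22:nrow(ds)       # skip the truncated-weight startup window
  above <- after[ds$tmax[after] > 20]
  below <- after[ds$tmax[after] <= 20]
  expect_lt(max(abs(mu[above] - 2 * cfg$baseline_rate)), 1e-10)
  expect_lt(max(abs(mu[below] - cfg$baseline_rate)), 1e-10)
})

test_that("truncated lag weights are renormalized over the startup window", {
  cfg <- sim_config(n_provinces = 1, years = 2000, baseline_rate = 10,
                    seasonal_amplitude = 0, dow_effects = rep(0, 7),
                    holiday_effect = 0, dispersion = 1,
                    temp_annual_amplitude = 0, temp_ar1 = 0, temp_sd = 0,
                    curve_heterogeneity_sd = 0, temp_province_range = NULL,
                    seed = 5)
  temps <- generate_temperature(cfg, 1)
  # constant temperature: any properly renormalized weighting gives the
  # same mean on every day, including the first 21
  truth <- true_association(function(x) rep(0.3, length(x)) * (x > 0),
                            reference_temp = -1)
  ds <- generate_counts(temps, truth, cfg)
  mu <- attr(ds, "mu")
  expect_lt(max(abs(mu - mu[22])), 1e-10)
})

test_that("lead-in mode removes the startup approximation entirely", {
  base <- list(n_provinces = 1, years = 2000, baseline_rate = 10,
               seasonal_amplitude = 0.1, dispersion = 1,
               curve_heterogeneity_sd = 0, temp_province_range = NULL,
               seed = 6)
  p_lead <- generate_panel(do.call(sim_config, c(base, lead_in = TRUE)),
                           percentile_truth())
  expect_equal(nrow(p_lead[[1]]), 366)  # 2000 is a leap year
  expect_equal(min(p_lead[[1]]$date), as.Date("2000-01-01"))
})

test_that("province temperature means are monotone across the gradient", {
  cfg <- sim_config(n_provinces = 10, years = 2000:2003,
                    temp_province_range = c(17, 26), seed = 7)
  means <- vapply(seq_len(10), function(i)
    mean(generate_temperature(cfg, i)$tmax), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1] - 17), 1)
  expect_lt(abs(means[10] - 26), 1)
})

test_that("panel structure and validation invariants hold", {
  cfg <- quick_config(n_provinces = 3)
  p <- generate_panel(cfg, percentile_truth())
  expect_length(p, 3)
  for (ds in p) {
    expect_s3_class(ds, "daily_series")
    expect_true(all(diff(as.numeric(ds$date)) == 1))
    expect_true(all(ds$tmin <= ds$tmax))
    expect_true(all(ds$count >= 0))
  }
  expect_length(generate_panel(quick_config(n_provinces = 1),
                               null_truth()), 1)
})

test_that("true_association enforces its invariants", {
  expect_error(true_association(function(x) x, lag_weights = rep(1, 22)),
               "sum to 1")
  expect_error(true_association(function(x) x, rep(1 / 21, 21)), "length 22")
  expect_error(true_association(function(x) x - 1, reference_temp = 5),
               "must be 0")
  w <- decaying_lag_weights()
  expect_length(w, 22)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0) && all(diff(w) < 0))
})

test_that("percentile-anchored truth hits its stated anchor points", {
  cfg <- quick_config(n_provinces = 1, years = 2000:2004,
                      temp_province_range = NULL)
  ds <- generate_temperature(cfg, 1)
  tr <- percentile_truth(35, 14, 75)(temperature_percentiles(ds, 0:100))
  q <- quantile(ds$tmax, c(.01, .75, .99), type = 7)
  expect_equal(tr$curve(q[[2]]), 0, tolerance = 1e-6)
  expect_equal(tr$curve(q[[1]]), log(1.35), tolerance = 0.02)
  expect_equal(tr$curve(q[[3]]), log(1.14), tolerance = 0.02)
})
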
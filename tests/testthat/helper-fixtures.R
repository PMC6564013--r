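# Shared fixtures and independent oracles used across the test files.

# A small simulation configuration for fast tests.
quick_config <- function(n_provinces = 2L, years = 2000:2001, seed = 1L, ...) {
  sim_config(n_provinces = n_provinces, years = years, seed = seed,
             baseline_rate = 15, ...)
}

# Literal textbook Cox-de Boor recursion, scalar and recursive on purpose:
# the brute-force oracle the vectorized implementation is checked against.
cdb_oracle <- function(x, knots, j, degree) {
  if (degree == 0) {
    # right-closed at the top of the knot range
    hi <- max(knots)
    if (knots[j] < knots[j + 1] &&
        (x >= knots[j] && (x < knots[j + 1] ||
                           (x == hi && knots[j + 1] == hi))))
      1 else 0
  } else {
    a <- 0
    if (knots[j + degree] > knots[j])
      a <- (x - knots[j]) / (knots[j + degree] - knots[j]) *
        cdb_oracle(x, knots, j, degree - 1)
    b <- 0
    if (knots[j + degree + 1] > knots[j + 1])
      b <- (knots[j + degree + 1] - x) /
        (knots[j + degree + 1] - knots[j + 1]) *
        cdb_oracle(x, knots, j + 1, degree - 1)
    a + b
  }
}

cdb_basis_oracle <- function(x, internal, boundary, degree) {
  knots <- c(rep(boundary[1], degree + 1), internal,
             rep(boundary[2], degree + 1))
  nb <- length(internal) + degree + 1
  out <- matrix(0, length(x), nb)
  for (r in seq_along(x))
    for (j in seq_len(nb))
      out[r, j] <- cdb_oracle(x[r], knots, j, degree)
  out
}

# Constant-temperature series helper.
constant_series <- function(tmax = 20, n = 120, province = "PX",
                            start = as.Date("2005-01-01")) {
  daily_series(province, start + 0:(n - 1), tmax = rep(tmax, n),
               tmin = rep(tmax - 8, n), count = 5L)
}

# A hand-built reduced_association for meta-analysis tests.
fake_reduced <- function(coef, vcov, id = "P01") {
  structure(list(coef = coef, vcov = vcov,
                 exposure_spec = basis_spec("quadratic-bspline",
                                            c(12, 20, 28), c(5, 35)),
                 temperature_summary = NULL,
                 province_id = id, period_label = NA_character_),
            class = "reduced_association")
}

# Truth with all lag mass at lag 0 and a log(2) step above a threshold.
step_truth <- function(threshold = 20) {
  true_association(
    function(x) ifelse(x > threshold, log(2), 0),
    lag_weights = c(1, rep(0, 21)),
    reference_temp = threshold - 5)
}
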
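test_that("a single province pools to itself with zero heterogeneity", {
  red <- fake_reduced(c(0.1, 0.2, 0.3, 0.4, 0.5), diag(0.01, 5))
  expect_warning(m <- meta_fit(list(red)), "single province")
  expect_lt(max(abs(m$fixed - red$coef)), 1e-8)
  expect_equal(m$psi, matrix(0, 5, 5))
})

test_that("identical provinces give fixed = coef, vcov = V/n, psi ~ 0", {
  V <- diag(0.04, 5)
  coef <- c(1, 2, 3, 4, 5) / 10
  reds <- lapply(1:20, function(i) fake_reduced(coef, V, sprintf("P%02d", i)))
  m <- meta_fit(reds)
  expect_lt(max(abs(m$fixed - coef)), 1e-8)
  expect_lt(max(abs(m$fixed_vcov - V / 20)), 1e-6)
  expect_lt(max(abs(m$psi)), 1e-6)
})

test_that("REML pooling at vx = 1 matches metafor's REML estimates", {
  set.seed(123)
  yi <- rnorm(12, 0.2, 0.15)
  sei <- runif(12, 0.05, 0.2)
  reds <- lapply(1:12, function(i)
    fake_reduced(yi[i], matrix(sei[i]^2, 1, 1), sprintf("P%02d", i)))
  mine <- meta_fit(reds)
  ref <- metafor::rma.uni(yi = yi, sei = sei, method = "REML",
                          control = list(tol = 1e-12))
  expect_lt(abs(mine$fixed - as.numeric(ref$beta)), 1e-4)
  expect_lt(abs(mine$psi[1, 1] - ref$tau2), 1e-4)
  expect_lt(abs(sqrt(mine$fixed_vcov[1, 1]) - ref$se), 1e-4)
})

test_that("multivariate REML matches metafor's rma.mv on shared inputs", {
  set.seed(77)
  k <- 3
  n <- 12
  theta <- c(0.5, -0.3, 0.2)
  Ss <- lapply(1:n, function(i) {
    A <- matrix(rnorm(9, 0, 0.3), 3, 3)
    crossprod(A) + diag(0.2, 3)
  })
  Y <- t(sapply(1:n, function(i) MASS::mvrnorm(1, theta, Ss[[i]])))
  mine <- meta_fit(lapply(1:n, function(i)
    fake_reduced(Y[i, ], Ss[[i]], sprintf("P%02d", i))))
  dat <- data.frame(yi = as.vector(t(Y)), outcome = factor(rep(1:k, n)),
                    study = rep(1:n, each = k))
  V <- matrix(0, n * k, n * k)
  for (i in 1:n) {
    idx <- (i - 1) * k + 1:k
    V[idx, idx] <- Ss[[i]]
  }
  ref <- metafor::rma.mv(yi, V, mods = ~ outcome - 1,
                         random = ~ outcome | study, struct = "UN",
                         data = dat, control = list(rel.tol = 1e-10))
  expect_lt(max(abs(mine$fixed - as.numeric(ref$beta))), 1e-4)
  expect_lt(max(abs(diag(mine$psi) - ref$tau2)), 1e-3)
  expect_lt(max(abs(sqrt(diag(mine$fixed_vcov)) - ref$se)), 1e-4)
})

test_that("pooled coefficients recover the known multivariate truth", {
  theta <- c(0.3, -0.2)
  Psi <- matrix(c(0.02, 0.005, 0.005, 0.01), 2, 2)
  set.seed(31)
  hits <- 0
  nrep <- 25
  for (r in seq_len(nrep)) {
    reds <- lapply(1:40, function(i) {
      S <- diag(runif(2, 0.005, 0.02))
      fake_reduced(MASS::mvrnorm(1, theta, Psi + S), S, sprintf("P%02d", i))
    })
    m <- meta_fit(reds)
    se <- sqrt(diag(m$fixed_vcov))
    if (all(abs(m$fixed - theta) < 2 * se)) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.75)
})

test_that("non-PSD province covariances are rejected", {
  bad <- fake_reduced(rep(0, 5), diag(c(1, 1, 1, 1, -1)))
  ok <- fake_reduced(rep(0, 5), diag(0.1, 5), "P02")
  expect_error(meta_fit(list(bad, ok)), "non-PSD")
})

test_that("BLUPs collapse to the pooled estimate when psi = 0", {
  V <- diag(0.04, 5)
  reds <- lapply(1:10, function(i)
    fake_reduced(rnorm(5, 0, 0.05), V, sprintf("P%02d", i)))
  m <- meta_fit(reds)
  m$psi <- matrix(0, 5, 5)
  b <- blup(m)
  for (bi in b) expect_lt(max(abs(bi$coef - m$fixed)), 1e-10)
})

test_that("BLUPs approach the province estimate as its vcov vanishes", {
  set.seed(41)
  coefs <- lapply(1:8, function(i) rnorm(5, 0, 0.3))
  reds <- lapply(1:8, function(i)
    fake_reduced(coefs[[i]], diag(0.05, 5), sprintf("P%02d", i)))
  reds[[1]] <- fake_reduced(coefs[[1]], diag(1e-10, 5), "P01")
  m <- meta_fit(reds)
  b <- blup(m)
  expect_lt(max(abs(b[[1]]$coef - coefs[[1]])), 1e-4)
})

test_that("BLUPs shrink toward the pooled estimate", {
  set.seed(42)
  reds <- lapply(1:10, function(i)
    fake_reduced(rnorm(5, 0, 0.3), diag(0.2, 5), sprintf("P%02d", i)))
  m <- meta_fit(reds)
  b <- blup(m)
  for (i in seq_along(b)) {
    d_raw <- m$y[i, ] - m$fixed
    d_blup <- b[[i]]$coef - m$fixed
    # shrinkage: the BLUP deviation never exceeds the raw deviation
    expect_lte(sqrt(sum(d_blup^2)), sqrt(sum(d_raw^2)) + 1e-10)
  }
})

test_that("pooled curve centering is exact and recentering is an involution", {
  p <- generate_panel(quick_config(n_provinces = 4, years = 2000:2002),
                      percentile_truth())
  fs <- run_first_stage(p)
  m <- meta_fit(fs$reduced)
  pool <- pooled_temperature_summary(p)
  cv <- pooled_curve(m, pool)
  ref <- cv$reference_percentile
  i <- match(ref, cv$grid$percentile)
  expect_identical(cv$grid$log_rr[i], 0)
  expect_identical(cv$grid$se[i], 0)
  cv_b <- recenter_curve(cv, 10)
  cv_back <- recenter_curve(cv_b, ref)
  expect_lt(max(abs(cv_back$grid$log_rr - cv$grid$log_rr)), 1e-12)
  expect_lt(max(abs(cv_back$grid$se - cv$grid$se)), 1e-12)

  # delta-method oracle: RR at p vs ref from the basis-difference contrast
  espec <- cv$exposure_spec
  xs <- summary_temperature(pool, c(5, ref))
  d <- bspline_basis(xs[1], espec) - bspline_basis(xs[2], espec)
  expect_equal(cv$grid$log_rr[cv$grid$percentile == 5],
               drop(d %*% m$fixed), tolerance = 1e-10)
  expect_equal(cv$grid$se[cv$grid$percentile == 5],
               sqrt(drop(d %*% m$fixed_vcov %*% t(d))), tolerance = 1e-10)
})

test_that("find_mhp matches a brute-force scan and handles edge shapes", {
  p <- generate_panel(quick_config(n_provinces = 3, years = 2000:2002),
                      percentile_truth())
  fs <- run_first_stage(p)
  m <- meta_fit(fs$reduced)
  cv <- pooled_curve(m, pooled_temperature_summary(p), reference = 50)
  expect_equal(find_mhp(cv), cv$grid$percentile[which.min(cv$grid$log_rr)])

  # constructed monotone decreasing curve -> boundary
  cv2 <- cv
  cv2$grid$log_rr <- seq(1, 0.01, length.out = 99)
  expect_equal(find_mhp(cv2), 99)
  # flat curve -> 50 with warning
  cv3 <- cv
  cv3$grid$log_rr <- rep(0, 99)
  expect_warning(expect_equal(find_mhp(cv3), 50), "flat")
  # symmetric tie -> toward the median
  cv4 <- cv
  cv4$grid$log_rr <- abs(cv$grid$percentile - 50) * 0 +
    pmin(abs(cv4$grid$percentile - 40), abs(cv4$grid$percentile - 60))
  expect_equal(find_mhp(cv4), 40)
})

test_that("percent change applies the exp transform and CI monotonicity", {
  p <- generate_panel(quick_config(n_provinces = 3, years = 2000:2002),
                      percentile_truth())
  fs <- run_first_stage(p)
  m <- meta_fit(fs$reduced)
  cv <- pooled_curve(m, pooled_temperature_summary(p))
  i <- match(1, cv$grid$percentile)
  cv$grid$log_rr[i] <- log(1.34)
  e <- percent_change(cv, 1)
  expect_equal(e$percent_change, 34, tolerance = 1e-10)
  expect_lte(e$ci_low, e$percent_change)
  expect_gte(e$ci_high, e$percent_change)
  expect_equal(e$label, "cold")

  ref <- percent_change(cv, cv$reference_percentile)
  expect_equal(ref$percent_change, 0)
  expect_equal(ref$ci_low, 0)
  expect_equal(ref$ci_high, 0)

  # widening the SE widens the interval
  cv$grid$se[i] <- 0.05
  e1 <- percent_change(cv, 1)
  cv$grid$se[i] <- 0.10
  e2 <- percent_change(cv, 1)
  expect_lt(e1$ci_high - e1$ci_low, e2$ci_high - e2$ci_low)
})

test_that("Wald comparison of identical pooled estimates is exactly null", {
  reds <- lapply(1:5, function(i)
    fake_reduced(rnorm(5), diag(0.1, 5), sprintf("P%02d", i)))
  m <- meta_fit(reds)
  w <- wald_compare(m, m)
  expect_equal(w$wald_statistic, 0)
  expect_equal(w$p_value, 1)
  expect_equal(w$df, 5L)
})

test_that("split_periods drops the excluded year from both periods", {
  p <- generate_panel(quick_config(n_provinces = 1, years = 1997:2013),
                      null_truth())
  sp <- split_periods(p, c(1997, 2002), c(2004, 2013), 2003)
  yr1 <- unique(format(sp$period1[[1]]$date, "%Y"))
  yr2 <- unique(format(sp$period2[[1]]$date, "%Y"))
  expect_equal(yr1, as.character(1997:2002))
  expect_equal(yr2, as.character(2004:2013))
  expect_false("2003" %in% c(yr1, yr2))

  # alternative split honoured; conservation when nothing is excluded
  sp2 <- split_periods(p, c(1997, 2004), c(2005, 2013), integer(0))
  expect_equal(nrow(sp2$period1[[1]]) + nrow(sp2$period2[[1]]),
               nrow(p[[1]]))
  expect_error(split_periods(p, c(1980, 1985), c(2004, 2013), 2003),
               "empty")
})
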
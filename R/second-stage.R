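#' Multivariate random-effects meta-analysis of reduced associations
#'
#' Intercept-only multivariate model: each province's reduced coefficient
#' vector is Normal(fixed, psi + vcov_i), with `psi` the between-province
#' covariance. `psi` is estimated by REML over a log-Cholesky
#' parameterization (guaranteeing positive semi-definiteness), started from
#' — and falling back to, on non-convergence — a method-of-moments
#' estimate. The pooled covariance is
#' `fixed_vcov = (sum_i (psi + vcov_i)^{-1})^{-1}`.
#'
#' @param reduced List of `reduced_association`s with a common basis
#'   dimension.
#' @param method `"reml"` (default) or `"mm"` (method of moments only).
#' @return A list of class `meta_result`: `fixed`, `fixed_vcov`, `psi`,
#'   `y` (province coefficient matrix), `S` (province covariances),
#'   `province_ids`, `q_statistic`, `q_df`, `method`, `converged`,
#'   `exposure_spec` (of the first input, for reference),
#'   `knot_percentiles`.
#' @export
meta_fit <- function(reduced, method = c("reml", "mm")) {
  method <- match.arg(method)
  stopifnot(length(reduced) >= 1)
  k <- length(reduced[[1]]$coef)
  Y <- do.call(rbind, lapply(reduced, function(r) {
    if (length(r$coef) != k) stopf("inputs have differing basis dimensions")
    matrix(r$coef, nrow = 1)
  }))
  S <- lapply(reduced, function(r) {
    if (!is_psd(r$vcov)) stopf("province %s has a non-PSD covariance",
                               r$province_id)
    (r$vcov + t(r$vcov)) / 2
  })
  ids <- vapply(reduced, function(r) r$province_id, character(1))
  n <- nrow(Y)
  espec <- reduced[[1]]$exposure_spec
  kp <- attr(espec, "knot_percentiles") %||% c(10, 50, 90)

  if (n == 1L) {
    warnf("single province: pooled estimate equals its input, psi set to 0")
    return(structure(list(fixed = Y[1, ], fixed_vcov = S[[1]],
                          psi = matrix(0, k, k), y = Y, S = S,
                          province_ids = ids, q_statistic = 0, q_df = 0L,
                          method = method, converged = TRUE,
                          exposure_spec = espec, knot_percentiles = kp),
                     class = "meta_result"))
  }

  gls_fixed <- function(psi) {
    Wsum <- matrix(0, k, k); b <- numeric(k)
    W <- vector("list", n)
    for (i in seq_len(n)) {
      W[[i]] <- chol2inv(chol(psi + S[[i]]))
      Wsum <- Wsum + W[[i]]
      b <- b + W[[i]] %*% Y[i, ]
    }
    Vfix <- chol2inv(chol(Wsum))
    list(fixed = drop(Vfix %*% b), fixed_vcov = Vfix, W = W, Wsum = Wsum)
  }

  # method-of-moments start/fallback: between-sample covariance minus the
  # average within-province covariance, floored to PSD
  Smean <- Reduce(`+`, S) / n
  psi_mm <- psd_floor(stats::cov(Y) - Smean, 0)

  par_to_L <- function(par) {
    L <- matrix(0, k, k)
    L[upper.tri(L, diag = TRUE)] <- par
    diag(L) <- exp(pmin(diag(L), 20))
    L
  }

  # negative restricted log-likelihood over the log-Cholesky
  # parameterization psi = L'L; also returns the analytic gradient
  # d(-lR)/dPsi = 0.5 (sum W_i - sum W_i R^-1 W_i - sum (W_i r_i)(W_i r_i)')
  # chained through L (envelope theorem removes the d beta terms).
  reml_eval <- function(par, want_grad = FALSE) {
    L <- par_to_L(par)
    psi <- crossprod(L)
    out <- tryCatch({
      ll <- 0; Wsum <- matrix(0, k, k); b <- numeric(k)
      W <- vector("list", n)
      for (i in seq_len(n)) {
        ch <- chol(psi + S[[i]])
        W[[i]] <- chol2inv(ch)
        ll <- ll + 2 * sum(log(diag(ch)))
        Wsum <- Wsum + W[[i]]
        b <- b + W[[i]] %*% Y[i, ]
      }
      chW <- chol(Wsum)
      Rinv <- chol2inv(chW)
      beta <- drop(Rinv %*% b)
      quad <- 0
      G <- if (want_grad) Wsum else NULL
      for (i in seq_len(n)) {
        r <- Y[i, ] - beta
        wr <- W[[i]] %*% r
        quad <- quad + drop(crossprod(r, wr))
        if (want_grad)
          G <- G - W[[i]] %*% Rinv %*% W[[i]] - tcrossprod(wr)
      }
      val <- 0.5 * (ll + 2 * sum(log(diag(chW))) + quad)
      grad <- NULL
      if (want_grad) {
        GL <- L %*% (G + t(G)) / 2
        gm <- GL
        diag(gm) <- diag(GL) * diag(L)
        grad <- gm[upper.tri(gm, diag = TRUE)]
      }
      list(value = val, grad = grad)
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value))
      list(value = 1e10, grad = if (want_grad) rep(0, length(par)) else NULL)
    else out
  }
  neg_reml <- function(par) reml_eval(par)$value
  neg_reml_grad <- function(par) reml_eval(par, want_grad = TRUE)$grad

  psi <- psi_mm
  converged <- TRUE
  used <- method
  if (method == "reml") {
    # strictly positive start: the log-Cholesky gradient vanishes at psi = 0,
    # so inflate a degenerate moment estimate by a fraction of the average
    # within-province variance to let the optimizer move
    ridge <- pmax(0.1 * diag(Smean), 1e-6)
    psi0 <- psi_mm + diag(ridge, k)
    L0 <- tryCatch(chol(psi0), error = function(e)
      diag(sqrt(diag(psi0)), k))
    par0 <- L0
    diag(par0) <- log(pmax(diag(L0), 1e-8))
    par0 <- par0[upper.tri(par0, diag = TRUE)]
    opt <- if (length(par0) == 1L) {
      tryCatch(stats::optim(par0, neg_reml, method = "Brent",
                            lower = -20, upper = 10),
               error = function(e) NULL)
    } else {
      tryCatch(stats::optim(par0, neg_reml, gr = neg_reml_grad,
                            method = "BFGS",
                            control = list(maxit = 200, reltol = 1e-10)),
               error = function(e) NULL)
    }
    if (is.null(opt) || !is.finite(opt$value)) {
      converged <- FALSE
      used <- "mm"
      warnf("REML optimization failed; falling back to method of moments")
    } else {
      L <- matrix(0, k, k)
      L[upper.tri(L, diag = TRUE)] <- opt$par
      diag(L) <- exp(pmin(diag(L), 20))
      psi <- crossprod(L)
    }
  }
  g <- gls_fixed(psi)

  # heterogeneity: Cochran-type Q at psi = 0
  g0 <- gls_fixed(matrix(0, k, k))
  q_stat <- 0
  for (i in seq_len(n)) {
    r <- Y[i, ] - g0$fixed
    q_stat <- q_stat + drop(crossprod(r, g0$W[[i]] %*% r))
  }

  structure(list(fixed = g$fixed, fixed_vcov = g$fixed_vcov,
                 psi = (psi + t(psi)) / 2, y = Y, S = S,
                 province_ids = ids,
                 q_statistic = q_stat, q_df = as.integer((n - 1) * k),
                 method = used, converged = converged,
                 exposure_spec = espec, knot_percentiles = kp),
            class = "meta_result")
}

#' Best linear unbiased predictions for each province
#'
#' `BLUP_i = fixed + psi (psi + vcov_i)^{-1} (coef_i - fixed)`: the
#' province estimate shrunk toward the pooled one in proportion to its
#' within-province uncertainty, letting sparse provinces borrow strength.
#'
#' @param meta A `meta_result`.
#' @return A list of `reduced_association`s (one per province) with BLUP
#'   coefficients and approximate covariances.
#' @export
blup <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  k <- length(meta$fixed)
  I <- diag(k)
  lapply(seq_along(meta$S), function(i) {
    A <- meta$psi %*% chol2inv(chol(meta$psi + meta$S[[i]]))
    coef <- drop(meta$fixed + A %*% (meta$y[i, ] - meta$fixed))
    V <- meta$psi - A %*% meta$psi +
      (I - A) %*% meta$fixed_vcov %*% t(I - A)
    structure(list(coef = coef, vcov = (V + t(V)) / 2,
                   exposure_spec = meta$exposure_spec,
                   temperature_summary = NULL,
                   province_id = meta$province_ids[i],
                   period_label = NA_character_),
              class = "reduced_association")
  })
}

#' Pooled overall cumulative exposure-response curve
#'
#' Evaluates the pooled coefficients on an exposure basis whose knots sit at
#' the pooled temperature percentiles, over an integer percentile grid, and
#' centers the curve at a reference percentile so the log relative risk (and
#' its delta-method standard error) is exactly zero there. By default the
#' reference is the minimum-hospitalizations percentile (MHP) found on the
#' provisional curve.
#'
#' @param meta A `meta_result`.
#' @param pooled_temps A `temperature_summary` (typically
#'   [pooled_temperature_summary()]).
#' @param reference Reference percentile, or `"mhp"` to locate it.
#' @param grid Integer percentile grid.
#' @return A list of class `pooled_curve`: `grid` (data frame `percentile,
#'   temp, log_rr, se`), `reference_percentile`, plus the basis and pooled
#'   estimates needed to recenter.
#' @export
pooled_curve <- function(meta, pooled_temps, reference = "mhp",
                         grid = 1:99) {
  stopifnot(inherits(meta, "meta_result"),
            inherits(pooled_temps, "temperature_summary"))
  espec <- exposure_spec_from_summary(pooled_temps, meta$knot_percentiles)
  temps <- summary_temperature(pooled_temps, grid)
  B <- eval_basis(temps, espec)
  curve <- structure(list(grid = data.frame(percentile = grid, temp = temps,
                                            log_rr = NA_real_, se = NA_real_),
                          reference_percentile = NA_integer_,
                          basis = B, fixed = meta$fixed,
                          fixed_vcov = meta$fixed_vcov,
                          exposure_spec = espec,
                          temperature_summary = pooled_temps),
                     class = "pooled_curve")
  ref <- if (identical(reference, "mhp")) {
    provisional <- recenter_curve(curve, grid[which.min(abs(grid - 50))])
    find_mhp(provisional)
  } else as.numeric(reference)
  recenter_curve(curve, ref)
}

#' Recenter a pooled curve at a new reference percentile
#'
#' Exact affine recentering: log-RR at percentile `p` becomes
#' `(B(x_p) - B(x_ref)) fixed`, with the delta-method standard error from
#' the same contrast. Recentering twice returns the original curve.
#'
#' @param curve A `pooled_curve`.
#' @param reference New reference percentile (must lie on the grid).
#' @return The recentered `pooled_curve`.
#' @export
recenter_curve <- function(curve, reference) {
  stopifnot(inherits(curve, "pooled_curve"))
  idx <- match(reference, curve$grid$percentile)
  if (is.na(idx)) stopf("reference percentile %s is not on the grid",
                        format(reference))
  D <- sweep(curve$basis, 2, curve$basis[idx, ])
  curve$grid$log_rr <- drop(D %*% curve$fixed)
  curve$grid$se <- sqrt(pmax(rowSums((D %*% curve$fixed_vcov) * D), 0))
  curve$grid$log_rr[idx] <- 0
  curve$grid$se[idx] <- 0
  curve$reference_percentile <- reference
  curve
}

#' Minimum-hospitalizations percentile (MHP)
#'
#' The percentile at which the pooled cumulative curve attains its minimum,
#' searched on the integer grid; ties are broken toward the median
#' percentile (then toward the lower percentile). A flat curve returns 50
#' with a warning.
#'
#' @param curve A `pooled_curve`.
#' @param search_range Length-2 percentile range to search.
#' @return The MHP (numeric).
#' @export
find_mhp <- function(curve, search_range = c(1, 99)) {
  stopifnot(inherits(curve, "pooled_curve"))
  g <- curve$grid
  keep <- g$percentile >= search_range[1] & g$percentile <= search_range[2]
  g <- g[keep, , drop = FALSE]
  if (diff(range(g$log_rr)) < 1e-12) {
    warnf("flat pooled curve: returning the median percentile")
    return(50)
  }
  minval <- min(g$log_rr)
  cand <- g$percentile[g$log_rr <= minval + 1e-12]
  cand[order(abs(cand - 50), cand)][1]
}

#' Percent change at a percentile versus the curve's reference
#'
#' Reports `100 * (exp(delta) - 1)` where `delta` is the centered log
#' relative risk at the percentile, with a normal-theory confidence
#' interval on the same scale. The label is `"cold"` below the reference
#' and `"heat"` above it.
#'
#' @param curve A centered `pooled_curve`.
#' @param percentile Percentile on the curve grid (e.g. 1 or 99).
#' @param alpha Two-sided significance level for the CI.
#' @return A list of class `effect_estimate`: `percentile`,
#'   `percent_change`, `ci_low`, `ci_high`, `se_log`,
#'   `reference_percentile`, `label`.
#' @export
percent_change <- function(curve, percentile, alpha = 0.05) {
  stopifnot(inherits(curve, "pooled_curve"))
  idx <- match(percentile, curve$grid$percentile)
  if (is.na(idx)) stopf("percentile %s is not on the grid", format(percentile))
  delta <- curve$grid$log_rr[idx]
  se <- curve$grid$se[idx]
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    percentile = percentile,
    percent_change = 100 * (exp(delta) - 1),
    ci_low = 100 * (exp(delta - z * se) - 1),
    ci_high = 100 * (exp(delta + z * se) - 1),
    se_log = se,
    reference_percentile = curve$reference_percentile,
    label = if (percentile < curve$reference_percentile) "cold"
    else if (percentile > curve$reference_percentile) "heat"
    else "reference"),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s effect at percentile %s vs MHP %s: %.1f%% (%.1f, %.1f)\n",
              x$label, format(x$percentile), format(x$reference_percentile),
              x$percent_change, x$ci_low, x$ci_high))
  invisible(x)
}

#' Wald test comparing two pooled associations
#'
#' `W = (f_a - f_b)' (V_a + V_b)^{-1} (f_a - f_b)` with a chi-square
#' reference on `vx` degrees of freedom; the two periods are treated as
#' independent (they use disjoint data). A singular summed covariance falls
#' back to the Moore-Penrose pseudo-inverse with rank-adjusted degrees of
#' freedom, with a warning.
#'
#' @param meta_a,meta_b `meta_result`s with the same basis dimension.
#' @param period_labels Optional length-2 labels.
#' @return A list of class `period_comparison`: `wald_statistic`, `df`,
#'   `p_value`, `period_labels`.
#' @export
wald_compare <- function(meta_a, meta_b,
                         period_labels = c("period1", "period2")) {
  stopifnot(inherits(meta_a, "meta_result"), inherits(meta_b, "meta_result"))
  if (length(meta_a$fixed) != length(meta_b$fixed))
    stopf("pooled coefficient vectors have different dimensions")
  d <- meta_a$fixed - meta_b$fixed
  V <- meta_a$fixed_vcov + meta_b$fixed_vcov
  k <- length(d)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(ev) * 1e-10)
  if (rank < k) {
    warnf("singular summed covariance: using pseudo-inverse with %d df", rank)
    W <- drop(t(d) %*% MASS::ginv(V) %*% d)
    df <- rank
  } else {
    W <- drop(t(d) %*% solve(V, d))
    df <- k
  }
  structure(list(wald_statistic = max(W, 0), df = as.integer(df),
                 p_value = stats::pchisq(max(W, 0), df, lower.tail = FALSE),
                 period_labels = period_labels),
            class = "period_comparison")
}

#' Split a panel into two calendar periods
#'
#' Date-filtered copies of every province, excluding the listed years from
#' both periods (the anomalously hot year is dropped entirely). Downstream
#' basis boundary knots are recomputed from each period's own data by
#' [run_first_stage()].
#'
#' @param panel List of `daily_series`.
#' @param period1,period2 Length-2 inclusive year ranges.
#' @param exclude Years excluded from both periods.
#' @return A list with elements `period1` and `period2`, each a panel.
#' @export
split_periods <- function(panel, period1 = c(1997, 2002),
                          period2 = c(2004, 2013), exclude = 2003) {
  take <- function(rng) {
    out <- lapply(panel, function(ds) {
      yr <- year_of(ds$date)
      keep <- yr >= rng[1] & yr <= rng[2] & !(yr %in% exclude)
      if (!any(keep)) return(NULL)
      sub <- ds[keep, , drop = FALSE]
      class(sub) <- c("daily_series", "data.frame")
      validate_daily_series(sub, allow_gaps = TRUE)
      sub
    })
    out[!vapply(out, is.null, logical(1))]
  }
  p1 <- take(period1)
  p2 <- take(period2)
  if (length(p1) == 0) stopf("period 1 is empty after filtering")
  if (length(p2) == 0) stopf("period 2 is empty after filtering")
  list(period1 = p1, period2 = p2)
}
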
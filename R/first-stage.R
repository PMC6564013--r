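#' Build the confounder design matrix for the province model
#'
#' Columns: intercept; six weekday indicators (Sunday is the reference);
#' holiday flag; influenza admission counts (omitted for respiratory-cause
#' runs, where influenza is part of the outcome); a natural cubic spline of
#' day of the year with `seasonality_df` degrees of freedom interacted with
#' calendar-year indicators (one seasonal curve per year); and a long-term
#' trend spline in time with one degree of freedom per decade (a single
#' linear term when the span is at most ten years). Constant/aliased-by-
#' construction columns (e.g. an all-zero holiday flag) are dropped and
#' logged in the `dropped` field.
#'
#' @param series A `daily_series`.
#' @param seasonality_df Seasonal degrees of freedom per year (>= 2).
#' @param adjust_influenza Include the influenza covariate?
#' @param trend_df Override the trend degrees of freedom (default
#'   `ceiling(years / 10)`).
#' @return A list of class `confounder_design`: `matrix`, `dropped`
#'   (character vector of dropped column names), `seasonality_df`,
#'   `trend_df`.
#' @export
build_confounder_design <- function(series, seasonality_df = 8L,
                                    adjust_influenza = TRUE,
                                    trend_df = NULL) {
  stopifnot(inherits(series, "daily_series"))
  if (seasonality_df < 2) stopf("seasonality_df must be >= 2")
  if (nrow(series) < 365) stopf("series must span at least one full year")
  doy <- day_of_year(series$date)
  yr <- year_of(series$date)
  years <- sort(unique(yr))
  n_years <- length(years)

  # seasonal spline: natural cubic, seasonality_df columns, interior knots
  # equally spaced over the day-of-year range
  sk <- seq(1, 366, length.out = seasonality_df + 1L)
  seas_spec <- basis_spec("natural-cubic",
                          internal_knots = sk[2:seasonality_df],
                          boundary = c(1, 366), intercept = FALSE)
  S1 <- eval_basis(doy, seas_spec)
  # one seasonal curve per calendar year (interaction with year indicators)
  seas <- matrix(0, nrow(series), seasonality_df * n_years)
  cn <- character(ncol(seas))
  for (k in seq_along(years)) {
    idx <- (k - 1L) * seasonality_df + seq_len(seasonality_df)
    seas[, idx] <- S1 * (yr == years[k])
    cn[idx] <- sprintf("seas%d.y%d", seq_len(seasonality_df), years[k])
  }
  colnames(seas) <- cn

  tim <- as.numeric(series$date - min(series$date)) / 365.25
  if (is.null(trend_df)) trend_df <- max(1L, as.integer(ceiling(n_years / 10)))
  if (trend_df == 1L) {
    trend <- matrix(tim - mean(tim), ncol = 1,
                    dimnames = list(NULL, "trend"))
  } else {
    tk <- seq(min(tim), max(tim), length.out = trend_df + 1L)
    trend <- eval_basis(tim, basis_spec("natural-cubic",
                                        internal_knots = tk[2:trend_df],
                                        boundary = range(tim),
                                        intercept = FALSE))
    colnames(trend) <- paste0("trend", seq_len(ncol(trend)))
  }

  dow <- matrix(0, nrow(series), 6,
                dimnames = list(NULL, paste0("dow", 1:6)))
  for (d in 1:6) dow[, d] <- as.numeric(series$dow == d)

  X <- cbind(`(Intercept)` = 1, dow,
             holiday = as.numeric(series$holiday))
  if (adjust_influenza) X <- cbind(X, influenza = as.numeric(series$influenza))
  X <- cbind(X, seas, trend)

  # drop degenerate (constant) columns other than the intercept
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2,
                        function(col) stats::sd(col) > 0))
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  structure(list(matrix = X, dropped = dropped,
                 seasonality_df = as.integer(seasonality_df),
                 trend_df = as.integer(trend_df)),
            class = "confounder_design")
}

#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Log-link Poisson-variance working model fitted by IRLS; the dispersion is
#' estimated afterwards as Pearson chi-square over residual degrees of
#' freedom and scales the covariance. Aliased columns are dropped via the
#' pivoted QR inside the weighted least-squares step and reported as `NA`
#' coefficients. The fitter never throws on numerical failure: it returns
#' `converged = FALSE`.
#'
#' @param y Non-negative integer response.
#' @param X Design matrix (including the intercept column).
#' @param tol Relative deviance-change convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return A list of class `qp_fit`: `coef` (with `NA` for aliased
#'   columns), `vcov` (dispersion-scaled, `NA` rows for aliased columns),
#'   `dispersion`, `fitted`, `deviance`, `rank`, `df_residual`, `converged`,
#'   `n_used`, `aliased`.
#' @export
fit_quasipoisson <- function(y, X, tol = 1e-8, maxit = 100L) {
  n <- length(y)
  p <- ncol(X)
  fail <- function() {
    list(coef = rep(NA_real_, p), vcov = matrix(NA_real_, p, p),
         dispersion = NA_real_, fitted = rep(NA_real_, n),
         deviance = NA_real_, rank = 0L, df_residual = n,
         converged = FALSE, n_used = n, aliased = rep(TRUE, p))
  }
  if (n <= p || sum(y) == 0) return(structure(fail(), class = "qp_fit"))
  mu <- y + mean(y) / 10 + 0.1
  eta <- log(mu)
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu
    z <- eta + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients[!is.na(fit$coefficients)])))
      return(structure(fail(), class = "qp_fit"))
    beta <- fit$coefficients
    beta0 <- ifelse(is.na(beta), 0, beta)
    eta_new <- drop(X %*% beta0)
    # step-halve only on numerical failure (non-finite deviance)
    step <- 1
    repeat {
      eta_try <- eta + step * (eta_new - eta)
      mu_try <- exp(pmin(eta_try, 700))
      dev_try <- 2 * sum(ifelse(y > 0, y * log(y / mu_try), 0) - (y - mu_try))
      if (is.finite(dev_try) || step < 1e-6) break
      step <- step / 2
    }
    if (!is.finite(dev_try)) return(structure(fail(), class = "qp_fit"))
    eta <- eta_try
    mu <- mu_try
    if (it > 1 && abs(dev - dev_try) / (abs(dev_try) + 0.1) < tol) {
      dev <- dev_try
      converged <- TRUE
      break
    }
    dev <- dev_try
  }
  beta <- fit$coefficients
  aliased <- is.na(beta)
  r <- fit$rank
  df_res <- n - r
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- pearson / df_res
  # unscaled covariance from the final weighted QR, mapped back through the
  # pivot; aliased columns get NA rows/columns
  R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_kept <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(r)]
  vcov <- matrix(NA_real_, p, p)
  vcov[piv, piv] <- dispersion * cov_kept
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, vcov = vcov, dispersion = dispersion,
                 fitted = mu, deviance = dev, rank = r,
                 df_residual = df_res, converged = converged, n_used = n,
                 aliased = aliased),
            class = "qp_fit")
}

#' Fit the province-specific distributed-lag model
#'
#' Quasi-Poisson regression of daily counts on the cross-basis block plus
#' the confounder design, restricted to rows with complete lag history. A
#' province is flagged not converged (never an exception) when the IRLS
#' fails, any cross-basis coefficient is aliased or non-finite, the
#' cross-basis covariance block is not positive semi-definite, or the
#' estimated dispersion exceeds `max_dispersion`.
#'
#' @param series A `daily_series` with counts.
#' @param crossbasis A `cross_basis` built on the same series.
#' @param design A `confounder_design` built on the same series.
#' @param max_dispersion Dispersion above which the fit is declared
#'   unstable.
#' @return A list of class `first_stage_fit`: `coef_full`, `vcov_full`
#'   (cross-basis block), `dispersion`, `converged`, `reason`, `n_used`,
#'   `province_id`, plus the full `qp_fit`.
#' @export
fit_province <- function(series, crossbasis, design, max_dispersion = 50) {
  stopifnot(inherits(series, "daily_series"),
            inherits(crossbasis, "cross_basis"),
            inherits(design, "confounder_design"))
  cb <- crossbasis$matrix
  X <- cbind(design$matrix, cb)
  rows <- crossbasis$complete & stats::complete.cases(X) & !is.na(series$count)
  n_used <- sum(rows)
  p <- ncol(X)
  if (n_used < p + 50)
    stopf("too few complete rows (%d) for %d columns", n_used, p)
  cb_idx <- ncol(design$matrix) + seq_len(ncol(cb))
  fit <- fit_quasipoisson(series$count[rows], X[rows, , drop = FALSE])
  coef_full <- fit$coef[cb_idx]
  vcov_full <- fit$vcov[cb_idx, cb_idx, drop = FALSE]
  reason <- NULL
  ok <- fit$converged
  if (!ok) reason <- "IRLS did not converge"
  else if (any(!is.finite(coef_full))) {
    ok <- FALSE; reason <- "aliased or non-finite cross-basis coefficients"
  } else if (!is_psd(vcov_full)) {
    ok <- FALSE; reason <- "cross-basis covariance not positive semi-definite"
  } else if (fit$dispersion > max_dispersion) {
    ok <- FALSE
    reason <- sprintf("dispersion %.1f exceeds %.0f", fit$dispersion,
                      max_dispersion)
  }
  structure(list(coef_full = coef_full, vcov_full = vcov_full,
                 dispersion = fit$dispersion, converged = ok,
                 reason = reason, n_used = n_used,
                 province_id = series$province[1], fit = fit),
            class = "first_stage_fit")
}

#' Run the first stage over a panel
#'
#' For each province: temperature percentiles, exposure basis with knots at
#' the 10th/50th/90th percentiles and boundary at the observed range, lag
#' basis with log-spaced knots up to `max_lag`, cross-basis, confounder
#' design, quasi-Poisson fit, and reduction to the overall cumulative
#' association. Provinces that do not converge are excluded from the
#' reduced list and reported.
#'
#' @param panel List of `daily_series`.
#' @param knot_percentiles Exposure knot percentiles.
#' @param max_lag Maximum lag (days).
#' @param lag_knots Number of log-scale lag knots.
#' @param seasonality_df Seasonal df per year.
#' @param adjust_influenza Include the influenza covariate (disable for
#'   respiratory-cause runs).
#' @param period_label Label stored on each reduced association.
#' @param trend_df Optional trend df override.
#' @return A list of class `first_stage_result`: `fits`, `reduced` (only
#'   converged provinces), `excluded` (data frame of id + reason).
#' @export
run_first_stage <- function(panel, knot_percentiles = c(10, 50, 90),
                            max_lag = 21L, lag_knots = 3L,
                            seasonality_df = 8L, adjust_influenza = TRUE,
                            period_label = NA_character_, trend_df = NULL) {
  stopifnot(length(panel) >= 1)
  lag_spec <- default_lag_spec(max_lag, lag_knots)
  fits <- list(); reduced <- list(); excluded <- list()
  for (ds in panel) {
    id <- ds$province[1]
    res <- tryCatch({
      ts <- temperature_percentiles(ds)
      espec <- exposure_spec_from_summary(ts, knot_percentiles)
      cb <- build_crossbasis(ds, espec, lag_spec, max_lag)
      des <- build_confounder_design(ds, seasonality_df, adjust_influenza,
                                     trend_df)
      fit <- fit_province(ds, cb, des)
      list(fit = fit, ts = ts, espec = espec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[id]] <- conditionMessage(res)
      next
    }
    fits[[id]] <- res$fit
    if (res$fit$converged) {
      reduced[[id]] <- reduce_overall(
        res$fit$coef_full, res$fit$vcov_full, res$espec, lag_spec,
        max_lag = max_lag, temperature_summary = res$ts,
        province_id = id, period_label = period_label)
    } else {
      excluded[[id]] <- res$fit$reason
    }
  }
  if (length(reduced) == 0)
    stopf("no province converged in the first stage")
  excluded_df <- if (length(excluded))
    data.frame(province = names(excluded),
               reason = unlist(excluded, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(province = character(), reason = character(),
                  stringsAsFactors = FALSE)
  structure(list(
    fits = fits, reduced = reduced,
    excluded = excluded_df,
    lag_spec = lag_spec, max_lag = as.integer(max_lag),
    knot_percentiles = knot_percentiles,
    period_label = period_label),
    class = "first_stage_result")
}

#' Summarize first-stage fits as a data frame
#'
#' @param result A `first_stage_result`.
#' @return Data frame `province, n_used, dispersion, converged`.
#' @export
first_stage_summary <- function(result) {
  do.call(rbind, lapply(result$fits, function(f)
    data.frame(province = f$province_id, n_used = f$n_used,
               dispersion = f$dispersion, converged = f$converged,
               stringsAsFactors = FALSE)))
}
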
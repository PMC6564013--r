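#' Basis specification
#'
#' Describes one marginal basis of the cross-basis tensor: either a
#' quadratic B-spline (used for the exposure-response dimension, knots at
#' temperature percentiles) or a natural cubic spline (used for the
#' lag-response dimension and for seasonality splines).
#'
#' @param kind `"quadratic-bspline"` or `"natural-cubic"`.
#' @param internal_knots Strictly increasing knots strictly inside
#'   `boundary` (degrees C for exposure, days for lag).
#' @param boundary Length-2 numeric boundary knots.
#' @param intercept Whether the basis spans the constant function.
#' @return A list of class `basis_spec` with the basis dimension in `$df`.
#' @export
basis_spec <- function(kind = c("quadratic-bspline", "natural-cubic"),
                       internal_knots, boundary, intercept = FALSE) {
  kind <- match.arg(kind)
  internal_knots <- as.numeric(internal_knots)
  boundary <- as.numeric(boundary)
  stopifnot(length(boundary) == 2, is_flag(intercept))
  if (boundary[1] >= boundary[2]) stopf("boundary must be increasing")
  if (length(internal_knots)) {
    if (is.unsorted(internal_knots, strictly = TRUE))
      stopf("internal knots must be strictly increasing")
    if (min(internal_knots) <= boundary[1] ||
        max(internal_knots) >= boundary[2])
      stopf("internal knots must lie strictly inside the boundary")
  }
  k <- length(internal_knots)
  df <- switch(kind,
               "quadratic-bspline" = k + 2L + intercept,
               "natural-cubic" = k + 1L + intercept)
  structure(list(kind = kind, internal_knots = internal_knots,
                 boundary = boundary, intercept = isTRUE(intercept),
                 df = as.integer(df)),
            class = "basis_spec")
}

# Cox-de Boor evaluation of the full B-spline basis of a given degree on
# the clamped knot vector (boundary knots repeated degree+1 times).
# Returns an n x (k + degree + 1) matrix. x must lie within the boundary.
bspline_full <- function(x, internal, boundary, degree) {
  knots <- c(rep(boundary[1], degree + 1), internal,
             rep(boundary[2], degree + 1))
  nb <- length(internal) + degree + 1L
  nk <- length(knots)
  # degree 0: indicator of the half-open knot intervals, right-closed at
  # the upper boundary
  B <- matrix(0, length(x), nk - 1L)
  for (j in seq_len(nk - 1L)) {
    if (knots[j + 1] > knots[j])
      B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
  }
  jlast <- max(which(diff(knots) > 0))
  B[x == boundary[2], jlast] <- 1
  if (degree == 0) return(B[, seq_len(nb), drop = FALSE])
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(x), ncol(B) - 1L)
    for (j in seq_len(ncol(Bn))) {
      den1 <- knots[j + d] - knots[j]
      den2 <- knots[j + d + 1] - knots[j + 1]
      term <- 0
      if (den1 > 0) term <- (x - knots[j]) / den1 * B[, j]
      if (den2 > 0) term <- term + (knots[j + d + 1] - x) / den2 * B[, j + 1]
      Bn[, j] <- term
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

# m-th derivative of the full B-spline basis via the standard derivative
# recursion D B_{j,p} = p * (B_{j,p-1}/(t_{j+p}-t_j) -
# B_{j+1,p-1}/(t_{j+p+1}-t_{j+1})).
bspline_full_deriv <- function(x, internal, boundary, degree, deriv = 1L) {
  if (deriv == 0) return(bspline_full(x, internal, boundary, degree))
  knots <- c(rep(boundary[1], degree + 1), internal,
             rep(boundary[2], degree + 1))
  lower <- bspline_full_deriv(x, internal, boundary, degree - 1L, deriv - 1L)
  # lower has k + degree columns indexed by the same knot vector shifted:
  # basis j of degree-1 over knots[2:(nk-1)] equals B_{j+1,degree-1} here.
  nb <- length(internal) + degree + 1L
  D <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) {
    den1 <- knots[j + degree] - knots[j]
    den2 <- knots[j + degree + 1] - knots[j + 1]
    term <- 0
    # B_{j,degree-1} on the full knot vector is column j-1 of the basis
    # built on knots without the first and last (clamped) knot
    if (den1 > 0 && j >= 2) term <- degree / den1 * lower[, j - 1]
    if (den2 > 0 && j <= ncol(lower)) term <- term - degree / den2 * lower[, j]
    D[, j] <- term
  }
  D
}

clip_to_boundary <- function(x, boundary, warn = TRUE) {
  out <- pmin(pmax(x, boundary[1]), boundary[2])
  n_clip <- sum(x < boundary[1] | x > boundary[2], na.rm = TRUE)
  if (warn && n_clip > 0)
    warnf("%d value(s) outside the basis boundary [%.2f, %.2f] were clipped",
          n_clip, boundary[1], boundary[2])
  out
}

#' Quadratic B-spline basis
#'
#' Degree-2 B-splines on the clamped knot sequence (boundary knots repeated
#' per Cox-de Boor). Values outside the boundary are clipped, with a
#' warning. With `intercept = TRUE` the full partition-of-unity basis of
#' dimension `k + 3` is returned; without it the first basis function is
#' dropped (dimension `k + 2`), the constant being absorbed by the model
#' intercept.
#'
#' @param x Numeric values at which to evaluate.
#' @param spec A `basis_spec` with `kind = "quadratic-bspline"`.
#' @return Matrix with `length(x)` rows and `spec$df` columns; `NA` inputs
#'   give `NA` rows.
#' @export
bspline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$kind != "quadratic-bspline")
    stopf("spec kind must be quadratic-bspline")
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- !is.na(x)
  xs <- clip_to_boundary(x[ok], spec$boundary)
  B <- bspline_full(xs, spec$internal_knots, spec$boundary, degree = 2L)
  if (!spec$intercept) B <- B[, -1L, drop = FALSE]
  out[ok, ] <- B
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' Natural cubic spline basis
#'
#' Cubic B-spline basis constrained to have zero second derivative at the
#' boundary knots and linear extrapolation beyond them. Dimension is
#' `k + 1` (plus one with `intercept = TRUE`), matching the usual natural
#' spline degrees of freedom.
#'
#' @inheritParams bspline_basis
#' @param spec A `basis_spec` with `kind = "natural-cubic"`.
#' @return Matrix with `length(x)` rows and `spec$df` columns.
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$kind != "natural-cubic") stopf("spec kind must be natural-cubic")
  b <- spec$boundary
  k <- length(spec$internal_knots)
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- !is.na(x)
  xs <- x[ok]
  n <- length(xs)
  full <- matrix(0, n, k + 4L)
  inside <- xs >= b[1] & xs <= b[2]
  if (any(inside))
    full[inside, ] <- bspline_full(xs[inside], spec$internal_knots, b, 3L)
  # linear extrapolation beyond the boundary: f(x) = f(b) + f'(b) (x - b)
  for (side in 1:2) {
    outside <- if (side == 1) xs < b[1] else xs > b[2]
    if (!any(outside)) next
    v0 <- bspline_full(b[side], spec$internal_knots, b, 3L)
    v1 <- bspline_full_deriv(b[side], spec$internal_knots, b, 3L, 1L)
    full[outside, ] <- rep(1, sum(outside)) %o% drop(v0) +
      (xs[outside] - b[side]) %o% drop(v1)
  }
  const <- rbind(bspline_full_deriv(b[1], spec$internal_knots, b, 3L, 2L),
                 bspline_full_deriv(b[2], spec$internal_knots, b, 3L, 2L))
  if (!spec$intercept) {
    full <- full[, -1L, drop = FALSE]
    const <- const[, -1L, drop = FALSE]
  }
  Q <- qr.Q(qr(t(const)), complete = TRUE)[, -(1:2), drop = FALSE]
  out[ok, ] <- full %*% Q
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  out
}

#' Evaluate a basis specification
#'
#' Dispatches to [bspline_basis()] or [natural_cubic_basis()].
#'
#' @inheritParams bspline_basis
#' @export
eval_basis <- function(x, spec) {
  switch(spec$kind,
         "quadratic-bspline" = bspline_basis(x, spec),
         "natural-cubic" = natural_cubic_basis(x, spec))
}

#' Log-scale lag knots
#'
#' Internal knots for the lag-response spline, equally spaced on the log
#' scale between lag 1 and the maximum lag:
#' `exp(k * log(max_lag) / (n_knots + 1))` for `k = 1..n_knots`.
#'
#' @param max_lag Maximum lag in days (>= 1).
#' @param n_knots Number of internal knots (>= 1).
#' @return Numeric vector of knots in `(1, max_lag)`.
#' @export
log_lag_knots <- function(max_lag = 21L, n_knots = 3L) {
  if (max_lag < 1) stopf("max_lag must be >= 1")
  if (n_knots < 1) stopf("n_knots must be >= 1")
  exp(seq_len(n_knots) * log(max_lag) / (n_knots + 1))
}

#' Default exposure basis for a temperature series
#'
#' Quadratic B-spline without intercept, internal knots at the given
#' percentiles of the series' daily maximum temperature and boundary knots
#' at its observed range.
#'
#' @param summary A `temperature_summary`.
#' @param knot_percentiles Percentiles for the internal knots.
#' @return A `basis_spec`.
#' @export
exposure_spec_from_summary <- function(summary,
                                       knot_percentiles = c(10, 50, 90)) {
  knots <- summary_temperature(summary, knot_percentiles)
  boundary <- summary_temperature(summary, c(0, 100))
  spec <- basis_spec("quadratic-bspline", internal_knots = knots,
                     boundary = boundary, intercept = FALSE)
  attr(spec, "knot_percentiles") <- knot_percentiles
  spec
}

#' Default lag basis
#'
#' Natural cubic spline over lags `0..max_lag` with an intercept and
#' internal knots equally spaced on the log-lag scale.
#'
#' @param max_lag Maximum lag (days).
#' @param n_knots Number of internal log-scale knots.
#' @return A `basis_spec`.
#' @export
default_lag_spec <- function(max_lag = 21L, n_knots = 3L) {
  basis_spec("natural-cubic", internal_knots = log_lag_knots(max_lag, n_knots),
             boundary = c(0, max_lag), intercept = TRUE)
}

#' Build the exposure-lag cross-basis
#'
#' The distributed-lag design block: row `t`, column `(i, j)` equals
#' `sum_{l=0..max_lag} Bx_i(x_{t-l}) * Bl_j(l)`, the tensor of the exposure
#' basis evaluated at lagged exposures with the lag basis evaluated at the
#' lag index. The first `max_lag` rows lack full lag history and are set to
#' `NA` (flagged in `$complete`), so the fitting stage excludes them.
#'
#' @param series A `daily_series` (its `tmax` is the exposure) or a plain
#'   numeric exposure vector.
#' @param exposure_spec,lag_spec `basis_spec`s for the two margins.
#' @param max_lag Maximum lag in days.
#' @return A list of class `cross_basis`: `matrix` (n x vx*vl), `complete`
#'   row flags, both specs, `lag_range`, `vx`, `vl`. Column `(i-1)*vl + j`
#'   pairs exposure function `i` with lag function `j`.
#' @export
build_crossbasis <- function(series, exposure_spec,
                             lag_spec = default_lag_spec(max_lag),
                             max_lag = 21L) {
  x <- if (inherits(series, "daily_series")) series$tmax else as.numeric(series)
  n <- length(x)
  if (n <= max_lag)
    stopf("series length (%d) must exceed the lag window (%d)", n, max_lag)
  Bx <- eval_basis(x, exposure_spec)
  Bl <- eval_basis(0:max_lag, lag_spec)
  vx <- ncol(Bx); vl <- ncol(Bl)
  # column (i, j) is the one-sided convolution of exposure-basis column i
  # with lag-basis column j: sum_l Bx_i(x_{t-l}) Bl_j(l). Computed as one
  # matrix product of the lag-embedded exposure basis with a kernel that
  # routes lag l of exposure function i onto column (i-1)*vl + j.
  cb <- matrix(NA_real_, n, vx * vl)
  E <- stats::embed(Bx, max_lag + 1L)   # row t: Bx[t, ], Bx[t-1, ], ...
  K <- matrix(0, (max_lag + 1L) * vx, vx * vl)
  for (l in 0:max_lag)
    for (i in seq_len(vx))
      K[l * vx + i, (i - 1L) * vl + seq_len(vl)] <- Bl[l + 1L, ]
  cb[(max_lag + 1L):n, ] <- E %*% K
  colnames(cb) <- paste0("cb.", rep(seq_len(vx), each = vl), ".",
                         rep(seq_len(vl), vx))
  structure(list(matrix = cb,
                 complete = c(rep(FALSE, max_lag), rep(TRUE, n - max_lag)),
                 exposure_spec = exposure_spec, lag_spec = lag_spec,
                 lag_range = c(0L, as.integer(max_lag)),
                 vx = vx, vl = vl),
            class = "cross_basis")
}

#' Reduce cross-basis coefficients to the overall cumulative association
#'
#' Contracts the full `vx * vl` coefficient vector (and covariance) over the
#' lag dimension: with `u_j = sum_{l=0..max_lag} Bl_j(l)`, the reduced
#' exposure coefficient `i` is `sum_j u_j * coef[(i,j)]`, and the covariance
#' transforms as `C V C'` for the corresponding contraction matrix `C`. The
#' result parameterizes the overall cumulative exposure-response curve on
#' the exposure basis.
#'
#' @param coef_full Length `vx * vl` coefficient vector, ordered as the
#'   cross-basis columns.
#' @param vcov_full Matching covariance matrix.
#' @param exposure_spec,lag_spec The cross-basis margins.
#' @param max_lag Maximum lag in days.
#' @param lag_basis Optional explicit lag-basis matrix
#'   (`(max_lag+1) x vl`) overriding `lag_spec` evaluation; intended for
#'   testing reductions against hand-built lag bases.
#' @param temperature_summary Optional `temperature_summary` carried along
#'   for downstream percentile grids.
#' @param province_id,period_label Optional labels.
#' @return A list of class `reduced_association`: `coef` (length vx),
#'   `vcov` (vx x vx), `exposure_spec`, labels.
#' @export
reduce_overall <- function(coef_full, vcov_full, exposure_spec,
                           lag_spec = default_lag_spec(max_lag),
                           max_lag = 21L, lag_basis = NULL,
                           temperature_summary = NULL,
                           province_id = NA_character_,
                           period_label = NA_character_) {
  Bl <- lag_basis %||% eval_basis(0:max_lag, lag_spec)
  vl <- ncol(Bl)
  vx <- exposure_spec$df
  if (length(coef_full) != vx * vl)
    stopf("coef_full has length %d; expected vx * vl = %d",
          length(coef_full), vx * vl)
  if (!all(dim(vcov_full) == length(coef_full)))
    stopf("vcov_full dimensions do not match coef_full")
  u <- colSums(Bl)
  C <- matrix(0, vx, vx * vl)
  for (i in seq_len(vx)) C[i, (i - 1L) * vl + seq_len(vl)] <- u
  coef <- drop(C %*% coef_full)
  vcov <- C %*% vcov_full %*% t(C)
  structure(list(coef = coef, vcov = (vcov + t(vcov)) / 2,
                 exposure_spec = exposure_spec,
                 temperature_summary = temperature_summary,
                 province_id = province_id, period_label = period_label),
            class = "reduced_association")
}
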
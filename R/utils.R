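# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily seeded RNG
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' that simulation functions are deterministic per seed without clobbering
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# streams (province x stage) while staying inside 32-bit integer range.
sub_seed <- function(seed, index, stream = 1L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + index * 7919 + stream * 104729
  as.integer(s %% 2147483562) + 1L
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Symmetrize and check positive semi-definiteness (within tolerance).
is_psd <- function(m, tol = 1e-8) {
  if (any(!is.finite(m))) return(FALSE)
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}

# Nearest PSD projection by eigenvalue flooring.
psd_floor <- function(m, floor = 0) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  (m2 + t(m2)) / 2
}

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

year_of <- function(dates) as.POSIXlt(dates)$year + 1900L

# 0 = Sunday .. 6 = Saturday; day 0 of the Date epoch was a Thursday
weekday_index <- function(dates) (as.integer(as.Date(dates)) + 4L) %% 7L
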
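# Internal numerical helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for the published change ratios (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_away(c(2.25, -2.25, 11.595), 1)
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  # nudge guards against representation error in x * m (e.g. 11.595 * 10)
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Multivariate normal draws: Cholesky factor when the covariance is PD,
# otherwise an eigenvalue square root with negative eigenvalues clipped at 0.
rmvn <- function(n, mean, sigma) {
  p <- length(mean)
  stopifnot(nrow(sigma) == p, ncol(sigma) == p)
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    message("covariance not positive definite; using eigenvalue square root")
    e <- eigen(sigma, symmetric = TRUE)
    R <- t(e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0))))
  }
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% R, 2, mean, "+")
}

# Month-day key ("MM-DD") used for day-of-year climatologies; keeps Feb 29
# distinct without relying on leap-dependent yday numbering.
mmdd <- function(dates) format(dates, "%m-%d")

# Calendar year as integer.
date_year <- function(dates) as.integer(format(dates, "%Y"))

# Validate a list of decades: non-overlapping closed [start, end] intervals,
# each spanning exactly 10 calendar years.
check_decades <- function(decades) {
  stopifnot(is.list(decades), length(decades) >= 1)
  spans <- vapply(decades, function(d) {
    stopifnot(length(d) == 2, d[2] >= d[1])
    d[2] - d[1] + 1
  }, numeric(1))
  if (any(spans != 10)) {
    stop("each decade must span exactly 10 calendar years")
  }
  starts <- vapply(decades, `[`, numeric(1), 1)
  ends <- vapply(decades, `[`, numeric(1), 2)
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-length(ends)])) {
    stop("decades must not overlap")
  }
  invisible(decades)
}

# Label like "2010-2019" for reporting.
decade_label <- function(d) sprintf("%d-%d", d[1], d[2])
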
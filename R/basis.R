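# Natural cubic spline bases for the exposure (temperature) and lag
# dimensions, and their row-wise tensor product: the cross-basis that encodes
# the bidimensional exposure-lag-response surface. Natural splines have
# linear tails beyond the boundary knots, which is also the extrapolation
# contract when projected temperatures exceed the historical range.

#' Specify a natural cubic spline basis
#'
#' @param internal_knots strictly increasing knot locations strictly inside
#'   the boundary pair (temperature in degrees C, or lag in days).
#' @param boundary_knots length-2 vector bracketing the evaluation range.
#' @param intercept logical; include the constant basis function.
#' @return a `spline_spec` list. Basis dimension is
#'   `length(internal_knots) + 1 + intercept`.
#' @export
spline_spec <- function(internal_knots, boundary_knots, intercept = FALSE) {
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  stopifnot(length(boundary_knots) == 2, boundary_knots[1] < boundary_knots[2])
  if (length(internal_knots)) {
    if (is.unsorted(internal_knots, strictly = TRUE)) {
      stop("internal knots must be strictly increasing")
    }
    if (min(internal_knots) <= boundary_knots[1] ||
        max(internal_knots) >= boundary_knots[2]) {
      stop("internal knots must lie strictly inside the boundary knots")
    }
  }
  structure(list(internal_knots = internal_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept)),
            class = "spline_spec")
}

#' Degrees of freedom of a spline specification
#' @param spec a [spline_spec()].
#' @return basis dimension (number of columns).
#' @export
spec_df <- function(spec) {
  length(spec$internal_knots) + 1L + as.integer(spec$intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the `length(x) x spec_df(spec)` basis matrix. Each basis function
#' has zero second derivative at and beyond the boundary knots, so values
#' outside the boundary are linear extrapolations.
#'
#' @param x numeric vector of evaluation points.
#' @param spec a [spline_spec()].
#' @return numeric matrix.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (length(spec$internal_knots)) {
    b <- splines::ns(x, knots = spec$internal_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  } else {
    b <- splines::ns(x, df = 1L + as.integer(spec$intercept),
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  }
  m <- matrix(as.numeric(b), nrow = length(x))
  if (any(!is.finite(m))) stop("non-finite basis values")
  m
}

#' Specify a cross-basis (exposure x lag tensor product)
#'
#' @param var_spec [spline_spec()] over temperature, conventionally without
#'   intercept (the overall curve is identified relative to a reference).
#' @param lag_spec [spline_spec()] over lag `0..max_lag`, conventionally with
#'   intercept.
#' @param max_lag maximum lag in days (default 21).
#' @return a `crossbasis_spec` list; the cross-basis has
#'   `spec_df(var_spec) * spec_df(lag_spec)` columns.
#' @export
crossbasis_spec <- function(var_spec, lag_spec, max_lag = 21L) {
  stopifnot(inherits(var_spec, "spline_spec"), inherits(lag_spec, "spline_spec"),
            max_lag >= 1)
  structure(list(var_spec = var_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag)),
            class = "crossbasis_spec")
}

#' Standard fixed-knots cross-basis for a temperature series
#'
#' Exposure basis: natural cubic spline with internal knots at given
#' percentiles of the fitting-period temperatures (default 10th/75th/90th)
#' and boundary knots at the observed min/max. Lag basis: natural cubic
#' spline on `0..max_lag` with `n_lag_knots` internal knots equally spaced on
#' the lag scale, with intercept.
#'
#' @param tmean fitting-period temperatures used for percentile knots and
#'   boundary knots.
#' @param var_percentiles exposure knot percentiles, in (0, 100).
#' @param n_lag_knots number of internal lag knots (default 2).
#' @param max_lag maximum lag in days (default 21).
#' @return a [crossbasis_spec()].
#' @export
default_crossbasis_spec <- function(tmean, var_percentiles = c(10, 75, 90),
                                    n_lag_knots = 2L, max_lag = 21L) {
  rng <- range(tmean)
  # type-7 quantiles: linear interpolation between order statistics
  kn <- unname(stats::quantile(tmean, var_percentiles / 100, type = 7))
  var_spec <- spline_spec(kn, rng, intercept = FALSE)
  lk <- seq(0, max_lag, length.out = n_lag_knots + 2L)
  lag_spec <- spline_spec(lk[-c(1, length(lk))], c(0, max_lag),
                          intercept = TRUE)
  crossbasis_spec(var_spec, lag_spec, max_lag)
}

#' Build the cross-basis matrix for a temperature series
#'
#' Row `t` holds, for exposure-basis column `i` and lag-basis column `j`
#' (column index `(i-1)*vl + j`), the sum over lags `l = 0..max_lag` of the
#' exposure basis evaluated at the temperature `l` days before `t` times the
#' lag basis at `l`. Rows without a complete lag window are `NA` and flagged
#' by `valid_from`.
#'
#' @param tmean temperature series (degrees C).
#' @param spec a [crossbasis_spec()].
#' @param history optional temperatures for the `max_lag` days preceding the
#'   series; when supplied every row is valid.
#' @return a `crossbasis` object: list with `matrix`, `spec`, `valid_from`.
#' @export
build_crossbasis <- function(tmean, spec, history = NULL) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  L <- spec$max_lag
  n <- length(tmean)
  if (n <= L) stop("series must be longer than max_lag")
  if (!is.null(history)) {
    if (length(history) < L) stop("history must supply max_lag days")
    x <- c(utils::tail(history, L), tmean)
    off <- L
  } else {
    x <- tmean
    off <- 0L
  }
  vx <- spec_df(spec$var_spec)
  vl <- spec_df(spec$lag_spec)
  C <- ns_basis(0:L, spec$lag_spec)              # (L+1) x vl
  B <- ns_basis(x, spec$var_spec)                # (n+off) x vx
  M <- matrix(NA_real_, n, vx * vl)
  valid_from <- if (off == L) 1L else L + 1L
  rows <- valid_from:n
  for (i in seq_len(vx)) {
    # lagged copies of exposure-basis column i, aligned to output rows
    lagmat <- vapply(0:L, function(l) B[rows + off - l, i], numeric(length(rows)))
    M[rows, (i - 1L) * vl + seq_len(vl)] <- lagmat %*% C
  }
  colnames(M) <- paste0("cb_v", rep(seq_len(vx), each = vl),
                        "_l", rep(seq_len(vl), vx))
  structure(list(matrix = M, spec = spec, valid_from = valid_from),
            class = "crossbasis")
}
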
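# Natural cubic spline bases and the DLNM cross-basis linking the exposure
# and lag dimensions.

#' Natural cubic spline specification
#'
#' Defines a natural cubic spline basis by its internal knots, boundary knots
#' and whether an intercept column is included. The basis dimension is
#' `length(knots) + 1 + intercept`.
#'
#' @param knots Numeric vector of internal knot positions, strictly
#'   increasing and strictly inside the boundary knots. May be empty.
#' @param boundary Numeric vector of length 2 with the boundary knots;
#'   the basis is linear beyond them (natural spline constraint).
#' @param intercept Logical; include an intercept column?
#'
#' @return An object of class `"spline_spec"`.
#' @export
spline_spec <- function(knots = numeric(0), boundary, intercept = FALSE) {
  knots <- as.numeric(knots)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2L || any(!is.finite(boundary)) ||
      boundary[1] >= boundary[2])
    stop("'boundary' must be two increasing finite values")
  if (length(knots)) {
    if (any(!is.finite(knots))) stop("'knots' must be finite")
    if (is.unsorted(knots, strictly = TRUE))
      stop("'knots' must be strictly increasing")
    if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
      stop("'knots' must lie strictly inside the boundary knots")
  }
  structure(list(knots = knots, boundary = boundary,
                 intercept = isTRUE(intercept)),
            class = "spline_spec")
}

#' Dimension of a spline or cross-basis specification
#'
#' @param spec A `"spline_spec"` or `"crossbasis_spec"` object.
#' @return Integer number of basis columns.
#' @export
spec_dim <- function(spec) {
  if (inherits(spec, "crossbasis_spec")) {
    lag_dim <- if (identical(spec$lag, "intercept")) 1L else spec_dim(spec$lag)
    return(spec_dim(spec$exposure) * lag_dim)
  }
  length(spec$knots) + 1L + as.integer(spec$intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Rows with missing `x` propagate as missing rows in the output. Values
#' beyond the boundary knots are extrapolated linearly, as implied by the
#' natural spline constraint.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param spec A [spline_spec()].
#' @return Matrix with `length(x)` rows and `spec_dim(spec)` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  ok <- !is.na(x)
  if (sum(ok) < 1L || length(unique(x[ok])) < 1L)
    stop("'x' must contain at least one non-missing value")
  out <- matrix(NA_real_, length(x), spec_dim(spec))
  out[ok, ] <- unclass(splines::ns(
    x[ok],
    knots = if (length(spec$knots)) spec$knots else NULL,
    Boundary.knots = spec$boundary,
    intercept = spec$intercept))
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' Lag knots equally spaced on the log scale
#'
#' Places `n_knots` internal knots at equally spaced positions on the log
#' scale between lag 1 and the maximum lag, the standard DLNM convention for
#' a lag-response spline (lag 0 is excluded because log 0 is undefined).
#'
#' @param n_knots Number of internal knots (>= 1).
#' @param maxlag Maximum lag in days (>= 2).
#' @return Numeric vector of knot positions, strictly increasing and inside
#'   `(1, maxlag)`.
#' @export
lag_knots_logscale <- function(n_knots = 3L, maxlag = 21L) {
  stopifnot(n_knots >= 1L, maxlag >= 2)
  g <- seq(log(1), log(maxlag), length.out = n_knots + 2L)
  exp(g[seq(2L, n_knots + 1L)])
}

#' Exposure spline specification from an observed series
#'
#' Places internal knots at percentiles of the observed distribution
#' (default 10th, 75th and 90th) with boundary knots at the observed range;
#' no intercept (it is absorbed by the regression model intercept).
#'
#' @param x Numeric exposure series (missing values ignored).
#' @param probs Percentile positions of the internal knots, as fractions.
#' @return A [spline_spec()].
#' @export
exposure_spec <- function(x, probs = c(0.10, 0.75, 0.90)) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("'x' has no non-missing values")
  spline_spec(knots = unname(stats::quantile(x, probs)),
              boundary = range(x), intercept = FALSE)
}

#' Cross-basis specification
#'
#' Combines an exposure spline (no intercept) and a lag spline (with
#' intercept) over lags `0..maxlag` into a bidimensional tensor
#' specification. With the defaults (3 exposure knots, 3 log-spaced lag
#' knots, 21 days of lag) the cross-basis has 4 x 5 = 20 columns.
#'
#' @param exposure A [spline_spec()] for the exposure dimension.
#' @param lag A [spline_spec()] for the lag dimension, the string
#'   `"intercept"` for a single constant lag-basis column (a plain moving
#'   sum over the lag window), or `NULL` for the default: 3 internal knots
#'   log-spaced over `(1, maxlag)`, boundary `c(0, maxlag)`, with intercept.
#' @param maxlag Maximum lag in days.
#' @return An object of class `"crossbasis_spec"`.
#' @export
crossbasis_spec <- function(exposure, lag = NULL, maxlag = 21L) {
  stopifnot(inherits(exposure, "spline_spec"), maxlag >= 0)
  if (is.null(lag)) {
    lag <- if (maxlag >= 2)
      spline_spec(lag_knots_logscale(3L, maxlag), boundary = c(0, maxlag),
                  intercept = TRUE)
    else "intercept"
  }
  if (!identical(lag, "intercept")) {
    stopifnot(inherits(lag, "spline_spec"))
    if (length(lag$knots) && (min(lag$knots) <= 0 || max(lag$knots) >= maxlag))
      stop("lag knots must lie inside (0, maxlag)")
  }
  structure(list(exposure = exposure, lag = lag, maxlag = as.integer(maxlag)),
            class = "crossbasis_spec")
}

#' Lag basis matrix of a cross-basis specification
#'
#' @param spec A [crossbasis_spec()].
#' @return Matrix with `maxlag + 1` rows (lags 0..maxlag) and one column per
#'   lag-basis function. When the lag spline carries an intercept, a column
#'   of ones is prepended ahead of the spline columns.
#' @keywords internal
lag_basis <- function(spec) {
  lags <- 0:spec$maxlag
  if (identical(spec$lag, "intercept"))
    return(matrix(1, length(lags), 1L))
  ns_basis(lags, spec$lag)
}

#' Build a DLNM cross-basis matrix
#'
#' Column (j, k) at day t holds `sum_l b_j(x[t - l]) * c_k(l)` over lags
#' `l = 0..maxlag`, where `b` is the exposure basis and `c` the lag basis.
#' The first `maxlag` rows, and any row whose lag window touches a missing
#' exposure, are set to `NA` (complete-window rule).
#'
#' @param x Daily exposure series, longer than `maxlag`.
#' @param spec A [crossbasis_spec()].
#' @return Matrix of class `"crossbasis"` with attributes `spec`.
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x)
  L <- spec$maxlag
  if (n <= L) stop("series length must exceed the maximum lag")
  if (all(is.na(x) | x < spec$exposure$boundary[1] |
          x > spec$exposure$boundary[2]))
    stop("all exposure values fall outside the boundary knots")
  B <- ns_basis(x, spec$exposure)
  C <- lag_basis(spec)
  Jb <- ncol(B); Jc <- ncol(C)
  Q <- matrix(0, n, Jb * Jc)
  for (l in 0:L) {
    Bl <- if (l == 0L) B else
      rbind(matrix(NA_real_, l, Jb), B[seq_len(n - l), , drop = FALSE])
    for (k in seq_len(Jc))
      Q[, (k - 1L) * Jb + seq_len(Jb)] <-
        Q[, (k - 1L) * Jb + seq_len(Jb), drop = FALSE] + Bl * C[l + 1L, k]
  }
  if (L > 0L) Q[seq_len(min(L, n)), ] <- NA_real_
  colnames(Q) <- paste0("cb.", rep(seq_len(Jb), Jc), ".",
                        rep(seq_len(Jc), each = Jb))
  structure(Q, spec = spec, class = c("crossbasis", "matrix", "array"))
}

#' Reduce cross-basis coefficients across the lag dimension
#'
#' Maps the bidimensional coefficient vector to the overall cumulative
#' (lag-summed) exposure-response coefficients: `eta_j = sum_k beta_jk *
#' sum_l c_k(l)`, with the covariance propagated through the same linear
#' map.
#'
#' @param coef Cross-basis coefficient vector (length `spec_dim(spec)`).
#' @param vcov Its covariance matrix.
#' @param spec The [crossbasis_spec()] used for fitting.
#' @return List with `eta` (length = exposure-basis dimension) and `vcov`.
#' @export
reduce_coef <- function(coef, vcov, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  Jb <- spec_dim(spec$exposure)
  csum <- colSums(lag_basis(spec))
  if (length(coef) != Jb * length(csum))
    stop("'coef' length does not match the cross-basis dimension")
  M <- kronecker(matrix(csum, ncol = 1L), diag(Jb))
  eta <- drop(crossprod(M, coef))
  V <- crossprod(M, vcov %*% M)
  V <- (V + t(V)) / 2
  list(eta = eta, vcov = V)
}

# Centred exposure-basis difference matrix: rows are b(x) - b(centre).
basis_diff <- function(x, spec, centre) {
  xx <- c(centre, x)
  Bb <- ns_basis(xx, spec)
  sweep(Bb[-1L, , drop = FALSE], 2L, Bb[1L, ], "-")
}

#' Predict the overall cumulative exposure-response curve
#'
#' Evaluates the cumulative log relative risk `[b(x) - b(centre)]' eta` on
#' a grid, with pointwise 95% confidence intervals from the delta method.
#' Accepts either reduced coefficients (length = exposure-basis dimension)
#' or full cross-basis coefficients (reduced internally).
#'
#' @param coef Coefficient vector (reduced or full cross-basis).
#' @param vcov Covariance matrix of `coef`.
#' @param spec A [spline_spec()] (exposure basis) or [crossbasis_spec()].
#' @param x_grid Exposure values at which to evaluate the curve.
#' @param centre Centring exposure; RR(centre) = 1 exactly.
#' @return Data frame with columns `x`, `logrr`, `se`, `rr`, `rr_low`,
#'   `rr_high`; attribute `"centre"` carries the centring value.
#' @export
predict_cumulative <- function(coef, vcov, spec, x_grid, centre) {
  if (inherits(spec, "crossbasis_spec")) {
    red <- reduce_coef(coef, vcov, spec)
    coef <- red$eta; vcov <- red$vcov; spec <- spec$exposure
  }
  stopifnot(inherits(spec, "spline_spec"),
            length(coef) == spec_dim(spec))
  if (centre < spec$boundary[1] || centre > spec$boundary[2])
    warning("centre lies outside the boundary knots; ",
            "curve extrapolated linearly")
  D <- basis_diff(x_grid, spec, centre)
  logrr <- drop(D %*% coef)
  se <- sqrt(pmax(rowSums((D %*% vcov) * D), 0))
  z <- stats::qnorm(0.975)
  out <- data.frame(x = x_grid, logrr = logrr, se = se,
                    rr = exp(logrr),
                    rr_low = exp(logrr - z * se),
                    rr_high = exp(logrr + z * se))
  attr(out, "centre") <- centre
  out
}
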
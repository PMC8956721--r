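# First-stage city-level quasi-Poisson time-series regression with the DLNM
# cross-basis, a seasonality/trend spline and day-of-week indicators, plus
# reduction to the overall cumulative association and the qAIC.

#' Build the first-stage design matrix for one city
#'
#' Columns: intercept + cross-basis (20 with the defaults) + natural cubic
#' spline of time with `season_df_per_year` df per year (rounded) + six
#' day-of-week indicators. Rows whose lag window touches a missing exposure
#' carry `NA` and are dropped at fitting time.
#'
#' @param city A [city_record()].
#' @param exposure `"station"` or `"reanalysis"`.
#' @param cb_spec Optional [crossbasis_spec()]; the default places exposure
#'   knots at the 10th/75th/90th percentiles of the chosen series with
#'   boundary knots at its range, and 3 log-spaced lag knots over 21 days.
#' @param season_df_per_year Degrees of freedom per year for the time
#'   spline (0 disables it).
#' @param dow Include day-of-week indicators?
#' @return Object of class `"fs_design"`: list with the design matrix `X`,
#'   response `y`, cross-basis column indices `cb_cols`, the cross-basis
#'   spec, the exposure series and dates.
#' @export
build_design <- function(city, exposure = c("station", "reanalysis"),
                         cb_spec = NULL, season_df_per_year = 8,
                         dow = TRUE) {
  stopifnot(inherits(city, "city_record"))
  exposure <- match.arg(exposure)
  x <- switch(exposure, station = city$data$temp_station,
              reanalysis = city$data$temp_reanalysis)
  if (all(is.na(x))) stop("exposure series is entirely missing")
  if (is.null(cb_spec)) cb_spec <- crossbasis_spec(exposure_spec(x))
  cb <- build_crossbasis(x, cb_spec)
  n <- nrow(city$data)
  parts <- list(`(Intercept)` = matrix(1, n, 1), cb = unclass(cb))
  sdf <- round(season_df_per_year * n / 365.25)
  if (sdf > 0) {
    tm <- unclass(splines::ns(seq_len(n), df = sdf))
    colnames(tm) <- paste0("time", seq_len(ncol(tm)))
    parts$time <- tm
  }
  if (dow) {
    wd <- factor(as.integer(format(city$data$date, "%u")), levels = 1:7)
    dm <- stats::model.matrix(~wd)[, -1, drop = FALSE]
    parts$dow <- dm
  }
  X <- do.call(cbind, parts)
  colnames(X)[1] <- "(Intercept)"
  structure(list(X = X, y = city$data$deaths,
                 cb_cols = 1L + seq_len(ncol(cb)), cb_spec = cb_spec,
                 exposure = x, exposure_choice = exposure,
                 dates = city$data$date, city = city$city),
            class = "fs_design")
}

#' Fit a quasi-Poisson regression
#'
#' IRLS via [stats::glm.fit()] with a log link; convergence on relative
#' deviance change below 1e-9 within 100 iterations. The dispersion is
#' estimated from the Pearson statistic, `phi = sum(r_P^2) / (n - k)`, and
#' scales the coefficient covariance. Aliased (rank-deficient) columns are
#' dropped with a warning.
#'
#' @param design An `"fs_design"` from [build_design()], or a numeric
#'   design matrix.
#' @param deaths Response counts (taken from `design` when omitted).
#' @return Object of class `"fs_fit"`: coefficients, covariance,
#'   `dispersion`, Poisson `loglik` at the fitted values, `deviance`, `k`
#'   (mean parameters), `n_obs`, `qaic`, fitted values, the rows used, and
#'   cross-basis bookkeeping when available.
#' @export
fit_quasipoisson <- function(design, deaths = NULL) {
  if (inherits(design, "fs_design")) {
    X <- design$X
    if (is.null(deaths)) deaths <- design$y
    meta <- design
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    meta <- NULL
  }
  if (any(!is.na(deaths) &
          (deaths < 0 | deaths != round(deaths))))
    stop("'deaths' must be non-negative integers")
  keep <- stats::complete.cases(X) & !is.na(deaths)
  Xk <- X[keep, , drop = FALSE]
  yk <- deaths[keep]
  if (!length(yk) || sum(yk) == 0)
    stop("no usable observations with non-zero deaths")
  qrX <- qr(Xk)
  dropped <- character(0)
  if (qrX$rank < ncol(Xk)) {
    aliased <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xk))]
    dropped <- colnames(Xk)[aliased]
    warning("dropping aliased column(s): ", paste(dropped, collapse = ", "))
    Xk <- Xk[, -aliased, drop = FALSE]
  }
  fit <- stats::glm.fit(Xk, yk, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-9,
                                                     maxit = 100))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance))
  mu <- fit$fitted.values
  k <- fit$rank
  n_obs <- length(yk)
  phi <- sum((yk - mu)^2 / mu) / (n_obs - k)
  p <- seq_len(k)
  cov_un <- chol2inv(fit$qr$qr[p, p, drop = FALSE])
  piv <- fit$qr$pivot[p]
  V <- matrix(NA_real_, ncol(Xk), ncol(Xk),
              dimnames = list(colnames(Xk), colnames(Xk)))
  V[piv, piv] <- phi * cov_un
  beta <- fit$coefficients
  ll <- sum(stats::dpois(yk, mu, log = TRUE))
  out <- structure(list(
    coefficients = beta, vcov = V, dispersion = phi,
    loglik = ll, deviance = fit$deviance, k = k, n_obs = n_obs,
    fitted = mu, y = yk, rows_used = which(keep),
    dropped = dropped,
    cb_cols = NULL, cb_spec = NULL, exposure = NULL,
    exposure_choice = NULL, city = NULL), class = "fs_fit")
  if (!is.null(meta)) {
    cb_names <- colnames(meta$X)[meta$cb_cols]
    out$cb_cols <- match(cb_names, colnames(Xk))
    if (anyNA(out$cb_cols))
      warning("cross-basis columns were aliased; reduction unavailable")
    out$cb_spec <- meta$cb_spec
    out$exposure <- meta$exposure
    out$exposure_choice <- meta$exposure_choice
    out$city <- meta$city
  }
  out$qaic <- compute_qaic(out)
  out
}

#' Quasi-Akaike information criterion
#'
#' `qAIC = -2 * logLik + 2 * k * phi`, with `logLik` the Poisson
#' log-likelihood at the fitted values, `k` the number of estimated mean
#' parameters (the dispersion is not counted) and `phi` the Pearson
#' dispersion. Comparable across models fitted to the same observations.
#'
#' @param fit An `"fs_fit"`.
#' @return The qAIC value.
#' @export
compute_qaic <- function(fit) {
  stopifnot(inherits(fit, "fs_fit"))
  -2 * fit$loglik + 2 * fit$k * fit$dispersion
}

#' Reduce a first-stage fit to the overall cumulative association
#'
#' Collapses the bidimensional cross-basis coefficients across the lag
#' dimension (see [reduce_coef()]), yielding the coefficients `eta` and
#' covariance `V` of the overall cumulative exposure-response curve: the
#' second-stage outcome for this city.
#'
#' @param fit An `"fs_fit"` fitted from an `"fs_design"`.
#' @return Object of class `"reduced_assoc"`: `eta`, `vcov`, the exposure
#'   [spline_spec()], exposure percentiles (0..100), range, and city id.
#' @export
reduce_to_overall_cumulative <- function(fit) {
  stopifnot(inherits(fit, "fs_fit"))
  if (is.null(fit$cb_cols) || anyNA(fit$cb_cols))
    stop("fit carries no (complete) cross-basis coefficient block")
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  if (anyNA(V)) stop("missing covariance block for the cross-basis")
  red <- reduce_coef(beta, V, fit$cb_spec)
  x <- fit$exposure[!is.na(fit$exposure)]
  structure(list(eta = red$eta, vcov = red$vcov,
                 spec = fit$cb_spec$exposure,
                 percentiles = stats::quantile(x, 0:100 / 100),
                 range = range(x), city = fit$city,
                 exposure_choice = fit$exposure_choice),
            class = "reduced_assoc")
}

#' Fit one city and reduce to the cumulative association
#'
#' Convenience wrapper chaining [build_design()], [fit_quasipoisson()] and
#' [reduce_to_overall_cumulative()].
#'
#' @inheritParams build_design
#' @return List with elements `fit` (`"fs_fit"`) and `assoc`
#'   (`"reduced_assoc"`).
#' @export
fit_city <- function(city, exposure = c("station", "reanalysis"),
                     cb_spec = NULL, season_df_per_year = 8, dow = TRUE) {
  des <- build_design(city, exposure, cb_spec, season_df_per_year, dow)
  fit <- fit_quasipoisson(des)
  list(fit = fit, assoc = reduce_to_overall_cumulative(fit))
}
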
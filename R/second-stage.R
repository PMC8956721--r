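# Multivariate multilevel meta-regression pooling the city-specific reduced
# coefficients, with two nested levels of random effects (city within
# country x climate-zone group), REML estimation on the log-Cholesky scale,
# BLUPs, and multilevel heterogeneity statistics.

#' Assemble a meta-analysis dataset
#'
#' Stacks the per-city reduced coefficients (`theta_i`) and within-city
#' covariances (`S_i`) with fixed-effect meta-predictors and the nested
#' grouping labels (city within country x climate-zone combinations).
#'
#' @param assocs List of `"reduced_assoc"` objects (see
#'   [reduce_to_overall_cumulative()]), one per city.
#' @param metadata Data frame with one row per city: `city`, `country`,
#'   `zone` plus any meta-predictor columns; row order must match
#'   `assocs`.
#' @param formula Right-hand-side formula for the fixed-effect
#'   meta-predictors (default intercept only).
#' @param scale_predictors Standardise non-constant numeric design columns
#'   internally for optimiser conditioning? Coefficients are reported on
#'   the original scale.
#' @return Object of class `"meta_dataset"`.
#' @export
meta_dataset <- function(assocs, metadata, formula = ~1,
                         scale_predictors = TRUE) {
  n <- length(assocs)
  stopifnot(n >= 1, nrow(metadata) == n)
  p <- length(assocs[[1]]$eta)
  theta <- vapply(assocs, function(a) a$eta, numeric(p))
  theta <- if (p == 1L) matrix(theta, ncol = 1L) else t(theta)
  S <- lapply(assocs, function(a) {
    if (!isTRUE(all.equal(dim(a$vcov), c(p, p))))
      stop("all within-city covariances must share dimension ", p)
    (a$vcov + t(a$vcov)) / 2
  })
  X <- stats::model.matrix(formula, data = metadata)
  if (nrow(X) != n) stop("meta-predictors contain missing values")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (scale_predictors && ncol(X) > 1) {
    for (j in seq_len(ncol(X))[-1]) {
      if (stats::sd(X[, j]) > 0 && length(unique(X[, j])) > 2) {
        ctr[j] <- mean(X[, j]); scl[j] <- stats::sd(X[, j])
        X[, j] <- (X[, j] - ctr[j]) / scl[j]
      }
    }
  }
  group <- interaction(metadata$country, metadata$zone, drop = TRUE)
  if (anyNA(group)) stop("grouping labels must be non-missing")
  structure(list(theta = theta, S = S, X = X, group = group,
                 city = as.character(metadata$city), p = p,
                 q = ncol(X), centre = ctr, scale = scl,
                 formula = formula, assocs = assocs),
            class = "meta_dataset")
}

# --- log-Cholesky parameterisation of a PSD matrix ---------------------------

psi_npar <- function(p, struct) switch(struct,
  unstr = p * (p + 1L) / 2L, diag = p, fixed = 0L)

psi_from_par <- function(par, p, struct) {
  if (struct == "diag") return(diag(exp(par)^2, p))
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

psi_to_par <- function(Psi, struct) {
  p <- nrow(Psi)
  if (struct == "diag") return(log(sqrt(pmax(diag(Psi), 1e-8))))
  e <- eigen(Psi, symmetric = TRUE)
  Psi <- e$vectors %*% diag(pmax(e$values, 1e-8), p) %*% t(e$vectors)
  L <- t(chol(Psi))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# Fixed-effect design for city i: mean(theta_i) = (I_p (x) x_i') vec(B).
x_design <- function(xrow, p) kronecker(diag(p), matrix(xrow, nrow = 1))

# Per-group marginal pieces used by the REML deviance and the BLUPs.
group_blocks <- function(md) {
  lapply(levels(md$group), function(g) {
    idx <- which(md$group == g)
    list(idx = idx,
         y = as.numeric(t(md$theta[idx, , drop = FALSE])),
         X = do.call(rbind, lapply(idx, function(i)
           x_design(md$X[i, ], md$p))),
         S = md$S[idx])
  })
}

group_V <- function(blk, Psi1, Psi2) {
  m <- length(blk$idx); p <- nrow(Psi1)
  V <- kronecker(matrix(1, m, m), Psi1)
  for (j in seq_len(m)) {
    r <- (j - 1L) * p + seq_len(p)
    V[r, r] <- V[r, r] + Psi2 + blk$S[[j]]
  }
  V
}

# Profiled (restricted) -2 log-likelihood up to an additive constant, with
# the GLS fixed effects solved exactly at each variance-parameter value.
meta_deviance <- function(par, md, blocks, struct, psi_fixed, reml) {
  p <- md$p
  n1 <- psi_npar(p, struct)
  Psi1 <- if (is.null(psi_fixed$Psi1))
    psi_from_par(par[seq_len(n1)], p, struct) else psi_fixed$Psi1
  i2 <- if (is.null(psi_fixed$Psi1)) n1 else 0L
  Psi2 <- if (is.null(psi_fixed$Psi2))
    psi_from_par(par[i2 + seq_len(psi_npar(p, struct))], p, struct)
    else psi_fixed$Psi2
  pq <- p * md$q
  A <- matrix(0, pq, pq); b <- numeric(pq)
  logdet <- 0; yy <- 0
  for (blk in blocks) {
    V <- group_V(blk, Psi1, Psi2)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Wy <- backsolve(ch, forwardsolve(t(ch), blk$y))
    WX <- backsolve(ch, forwardsolve(t(ch), blk$X))
    A <- A + crossprod(blk$X, WX)
    b <- b + crossprod(blk$X, Wy)
    yy <- yy + sum(blk$y * Wy)
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(1e10)
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  quad <- yy - sum(b * beta)
  dev <- logdet + quad
  if (reml) dev <- dev + 2 * sum(log(diag(chA)))
  if (!is.finite(dev)) return(1e10)
  attr(dev, "beta") <- beta
  attr(dev, "vcov_beta") <- chol2inv(chA)
  attr(dev, "Psi") <- list(Psi1 = Psi1, Psi2 = Psi2)
  dev
}

#' Fit the multivariate multilevel meta-regression
#'
#' Marginal model `theta_i ~ N(X_i vec(B), S_i + Psi2 + Psi1[group])` with
#' independent random effects at the city level (`Psi2`) and the country x
#' climate-zone level (`Psi1`, shared by cities in the same group).
#' Variance components are optimised on the log-Cholesky scale by
#' quasi-Newton (BFGS) on the profiled (restricted) likelihood; fixed
#' effects are the exact GLS solution at the optimum.
#'
#' @param md A [meta_dataset()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param struct Random-effect covariance structure at both levels:
#'   `"unstr"` (unstructured), `"diag"`, or `"fixed"` (both frozen at 0,
#'   i.e. fixed-effects meta-regression).
#' @param psi_fixed Optional list with `Psi1` and/or `Psi2` matrices to
#'   hold fixed (e.g. zero matrices) while estimating the rest.
#' @param control Passed to [stats::optim()].
#' @return Object of class `"meta_fit"`: fixed effects `B` (q x p, on the
#'   original predictor scale), `vcov_beta`, `Psi1`, `Psi2`, the restricted
#'   log-likelihood (up to a constant), and a convergence flag.
#' @export
fit_meta <- function(md, method = c("REML", "ML"),
                     struct = c("unstr", "diag", "fixed"),
                     psi_fixed = list(), control = list()) {
  stopifnot(inherits(md, "meta_dataset"))
  method <- match.arg(method)
  struct <- match.arg(struct)
  p <- md$p
  if (struct != "fixed" && length(md$S) < 2)
    stop("need at least 2 cities to estimate random effects")
  blocks <- group_blocks(md)
  zero <- matrix(0, p, p)
  if (struct == "fixed") psi_fixed <- list(Psi1 = zero, Psi2 = zero)
  reml <- method == "REML"
  free1 <- is.null(psi_fixed$Psi1); free2 <- is.null(psi_fixed$Psi2)
  npar <- (free1 + free2) * psi_npar(p, struct)
  if (npar == 0L) {
    dev <- meta_deviance(numeric(0), md, blocks, struct, psi_fixed, reml)
    opt <- list(par = numeric(0), convergence = 0L, value = as.numeric(dev))
  } else {
    # start from a moment split of the excess dispersion of theta
    R <- stats::cov(md$theta)
    if (md$p == 1L) R <- matrix(stats::var(md$theta[, 1]), 1, 1)
    Sbar <- Reduce(`+`, md$S) / length(md$S)
    excess <- R - Sbar
    e <- eigen((excess + t(excess)) / 2, symmetric = TRUE)
    excess <- e$vectors %*% diag(pmax(e$values, 1e-4), p) %*% t(e$vectors)
    par0 <- c(if (free1) psi_to_par(excess / 2, struct),
              if (free2) psi_to_par(excess / 2, struct))
    ctl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
    opt <- stats::optim(par0, function(z)
      as.numeric(meta_deviance(z, md, blocks, struct, psi_fixed, reml)),
      method = "BFGS", control = ctl)
    if (opt$convergence != 0L)
      warning("variance-component optimisation did not fully converge (code ",
              opt$convergence, ")")
  }
  dev <- meta_deviance(opt$par, md, blocks, struct, psi_fixed, reml)
  beta <- attr(dev, "beta")
  Psi <- attr(dev, "Psi")
  # back-transform fixed effects to the original predictor scale
  B_std <- matrix(beta, nrow = md$q, ncol = p,
                  dimnames = list(colnames(md$X), NULL))
  B <- B_std
  if (md$q > 1) {
    for (j in seq_len(md$q)[-1]) {
      B[j, ] <- B_std[j, ] / md$scale[j]
      B[1, ] <- B[1, ] - B_std[j, ] * md$centre[j] / md$scale[j]
    }
  }
  structure(list(B = B, B_std = B_std, vcov_beta = attr(dev, "vcov_beta"),
                 Psi1 = Psi$Psi1, Psi2 = Psi$Psi2,
                 logLik = -0.5 * as.numeric(dev), method = method,
                 struct = struct, converged = opt$convergence == 0L,
                 md = md), class = "meta_fit")
}

#' Pooled coefficients at a covariate profile
#'
#' @param object A `"meta_fit"`.
#' @param newdata One-row data frame of meta-predictors (original scale);
#'   omitted for an intercept-only model.
#' @param ... Unused.
#' @return Numeric vector of pooled outcome coefficients (length p).
#' @export
predict.meta_fit <- function(object, newdata = NULL, ...) {
  md <- object$md
  x <- if (is.null(newdata)) {
    if (md$q != 1) stop("'newdata' required for models with predictors")
    matrix(1, 1, 1)
  } else {
    stats::model.matrix(md$formula, data = newdata)
  }
  if (ncol(x) != md$q) stop("'newdata' does not match the fitted predictors")
  drop(x[1, , drop = FALSE] %*% object$B)
}

#' Best linear unbiased predictions of city-specific associations
#'
#' Posterior means of the city-specific true coefficients given the
#' observed `theta_i`, the fitted fixed effects and variance components,
#' computed by a joint GLS solve per group (both nested levels at once).
#' In the scalar single-level case this reduces to
#' `eta_i = mu_i + psi / (psi + s_i) * (theta_i - mu_i)`.
#'
#' @param fit A `"meta_fit"`.
#' @return List of `"reduced_assoc"` objects (one per city, in dataset
#'   order) carrying the BLUP coefficients and their conditional
#'   covariance, with the city's exposure basis spec and percentiles.
#' @export
compute_blups <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  md <- fit$md
  p <- md$p
  beta <- as.numeric(fit$B_std)
  blocks <- group_blocks(md)
  out <- vector("list", length(md$city))
  for (blk in blocks) {
    m <- length(blk$idx)
    V <- group_V(blk, fit$Psi1, fit$Psi2)
    r <- blk$y - as.numeric(blk$X %*% beta)
    Vinv_r <- solve(V, r)
    for (j in seq_len(m)) {
      i <- blk$idx[j]
      Ki <- kronecker(matrix(1, 1, m), fit$Psi1)
      Ki[, (j - 1L) * p + seq_len(p)] <-
        Ki[, (j - 1L) * p + seq_len(p), drop = FALSE] + fit$Psi2
      mu_i <- as.numeric(x_design(md$X[i, ], p) %*% beta)
      eta <- mu_i + as.numeric(Ki %*% Vinv_r)
      Vc <- fit$Psi1 + fit$Psi2 - Ki %*% solve(V, t(Ki))
      Vc <- (Vc + t(Vc)) / 2
      a <- md$assocs[[i]]
      out[[i]] <- structure(list(eta = eta, vcov = Vc, spec = a$spec,
                                 percentiles = a$percentiles,
                                 range = a$range, city = a$city,
                                 exposure_choice = a$exposure_choice),
                            class = "reduced_assoc")
    }
  }
  out
}

#' Multilevel heterogeneity statistics
#'
#' Cochran's multivariate Q from the fixed-effects (GLS, `Psi = 0`) fit:
#' `Q = sum_i (theta_i - X_i beta)' S_i^{-1} (theta_i - X_i beta)`, with
#' `df = n p - q p` and `I2 = max(0, 100 (Q - df) / Q)` percent.
#'
#' @param md A [meta_dataset()].
#' @return List with `Q`, `df`, `I2` (percent) and the chi-square
#'   `p_value`.
#' @export
heterogeneity_stats <- function(md) {
  stopifnot(inherits(md, "meta_dataset"))
  p <- md$p; pq <- p * md$q
  A <- matrix(0, pq, pq); b <- numeric(pq)
  Winv <- vector("list", length(md$S))
  for (i in seq_along(md$S)) {
    Wi <- tryCatch(solve(md$S[[i]]), error = function(e)
      stop("singular within-city covariance for city ", md$city[i]))
    Winv[[i]] <- Wi
    Xi <- x_design(md$X[i, ], p)
    A <- A + t(Xi) %*% Wi %*% Xi
    b <- b + t(Xi) %*% Wi %*% md$theta[i, ]
  }
  beta <- solve(A, b)
  Q <- 0
  for (i in seq_along(md$S)) {
    ri <- md$theta[i, ] - as.numeric(x_design(md$X[i, ], p) %*% beta)
    Q <- Q + as.numeric(t(ri) %*% Winv[[i]] %*% ri)
  }
  df <- length(md$S) * p - pq
  list(Q = Q, df = df, I2 = max(0, 100 * (Q - df) / Q),
       p_value = stats::pchisq(Q, df, lower.tail = FALSE))
}
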
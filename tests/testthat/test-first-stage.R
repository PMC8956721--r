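# First-stage quasi-Poisson regression, reduction, qAIC.

test_that("design matrix bookkeeping matches the model formulation", {
  cfg <- sim_config(n_cities = 1, years = 1, seed = 2)
  ct <- simulate_study(cfg)$cities[[1]]
  des <- build_design(ct, "station")
  expect_equal(ncol(des$X), 1L + 20L + 8L + 6L)
  des0 <- build_design(ct, "station", season_df_per_year = 0, dow = FALSE)
  expect_equal(ncol(des0$X), 21L)
  # each day-of-week indicator sums to ~ n/7
  dowcols <- grep("^wd", colnames(des$X))
  expect_length(dowcols, 6L)
  n <- nrow(des$X)
  for (j in dowcols)
    expect_equal(sum(des$X[, j]), n / 7, tolerance = 0.02)
  # 3 years -> 24 df for the time spline
  cfg3 <- sim_config(n_cities = 1, years = 3, seed = 2)
  ct3 <- simulate_study(cfg3)$cities[[1]]
  expect_equal(ncol(build_design(ct3, "station")$X), 1L + 20L + 24L + 6L)
})

test_that("intercept-only quasi-Poisson fit has the closed-form MLE", {
  y <- c(3, 5, 2, 8, 4, 6, 2, 1)
  fit <- fit_quasipoisson(matrix(1, length(y), 1), y)
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-10)
  expect_equal(fit$k, 1L)
  expect_error(fit_quasipoisson(matrix(1, 3, 1), c(1, -2, 1)),
               "non-negative")
  expect_error(fit_quasipoisson(matrix(1, 3, 1), c(0, 0, 0)), "non-zero")
})

test_that("quasi-Poisson recovers a known GLM with unit dispersion", {
  set.seed(71)
  n <- 5000
  X <- cbind(1, rnorm(n), runif(n))
  beta <- c(2, 0.3, -0.5)
  y <- rpois(n, exp(X %*% beta))
  fit <- fit_quasipoisson(X, y)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
})

test_that("fit matches an independently coded Newton-Raphson oracle", {
  set.seed(72)
  X <- cbind(1, rnorm(10))
  y <- rpois(10, exp(1 + 0.5 * X[, 2]))
  y[1] <- y[1] + 1  # ensure non-degenerate
  fit <- fit_quasipoisson(X, y)
  # oracle: straight Newton-Raphson on the Poisson score
  b <- c(log(mean(y)), 0)
  for (it in 1:50) {
    mu <- as.numeric(exp(X %*% b))
    score <- crossprod(X, y - mu)
    info <- crossprod(X, X * mu)
    b <- b + solve(info, score)
  }
  expect_equal(unname(fit$coefficients), as.numeric(b), tolerance = 1e-8)
})

test_that("dispersion follows the Pearson definition and scales SEs", {
  set.seed(73)
  cfg1 <- sim_config(n_cities = 1, years = 3, overdispersion = 1,
                     seed = 31)
  cfg3 <- sim_config(n_cities = 1, years = 3, overdispersion = 3,
                     seed = 31)
  f1 <- fit_city(simulate_study(cfg1)$cities[[1]], "station")$fit
  f3 <- fit_city(simulate_study(cfg3)$cities[[1]], "station")$fit
  expect_equal(f3$dispersion / f1$dispersion, 3, tolerance = 0.35)
  # SEs scale by ~ sqrt(phi ratio)
  r <- sqrt(diag(f3$vcov)[1] / diag(f1$vcov)[1])
  expect_equal(unname(r), sqrt(f3$dispersion / f1$dispersion),
               tolerance = 0.15)
  # Pearson definition holds exactly
  expect_equal(f1$dispersion,
               sum((f1$y - f1$fitted)^2 / f1$fitted) /
                 (f1$n_obs - f1$k))
})

test_that("aliased columns are dropped with a warning", {
  set.seed(74)
  x <- rnorm(100)
  X <- cbind(1, x, 2 * x)
  colnames(X) <- c("a", "b", "c")
  y <- rpois(100, exp(1 + 0.2 * x))
  expect_warning(fit <- fit_quasipoisson(X, y), "aliased")
  expect_equal(fit$k, 2L)
})

test_that("reduction to the overall cumulative curve matches the lag-sum oracle", {
  cfg <- sim_config(n_cities = 1, years = 3, seed = 41)
  ct <- simulate_study(cfg)$cities[[1]]
  res <- fit_city(ct, "station")
  fit <- res$fit; assoc <- res$assoc
  expect_length(assoc$eta, 4L)
  expect_equal(dim(assoc$vcov), c(4L, 4L))
  expect_true(isSymmetric(assoc$vcov))
  expect_true(all(eigen(assoc$vcov)$values > -1e-12))
  # oracle: predict from the full 20-dim coefficients (internal reduction
  # route already tested against the double loop in test-basis)
  grid <- seq(assoc$percentiles[["5%"]], assoc$percentiles[["95%"]],
              length.out = 50)
  centre <- assoc$percentiles[["50%"]]
  full <- predict_cumulative(fit$coefficients[fit$cb_cols],
                             fit$vcov[fit$cb_cols, fit$cb_cols],
                             fit$cb_spec, grid, centre)
  red <- predict_cumulative(assoc$eta, assoc$vcov, assoc$spec, grid,
                            centre)
  expect_equal(red$logrr, full$logrr, tolerance = 1e-10)
  expect_equal(red$se, full$se, tolerance = 1e-10)
})

test_that("zero cross-basis coefficients reduce to a flat curve", {
  spec <- crossbasis_spec(spline_spec(knots = c(8, 12, 16),
                                      boundary = c(0, 25)))
  red <- reduce_coef(rep(0, 20), diag(20), spec)
  expect_equal(red$eta, rep(0, 4))
  pred <- predict_cumulative(red$eta, red$vcov, spec$exposure,
                             seq(2, 24, 1), 12)
  expect_equal(pred$rr, rep(1, nrow(pred)))
})

test_that("qAIC reduces to AIC for Poisson data and matches hand computation", {
  set.seed(75)
  y <- rpois(200, 5)
  fit <- fit_quasipoisson(matrix(1, 200, 1), y)
  g <- glm(y ~ 1, family = poisson)
  fit$dispersion <- 1
  expect_equal(compute_qaic(fit), AIC(g), tolerance = 1e-8)

  # 5-observation hand example, intercept only
  y5 <- c(1, 2, 3, 2, 1)
  f5 <- fit_quasipoisson(matrix(1, 5, 1), y5)
  mu <- mean(y5)
  phi <- sum((y5 - mu)^2 / mu) / 4
  by_hand <- -2 * sum(dpois(y5, mu, log = TRUE)) + 2 * 1 * phi
  expect_equal(compute_qaic(f5), by_hand, tolerance = 1e-10)
})

test_that("adding a covariate changes qAIC by 2 phi minus the deviance drop", {
  set.seed(76)
  n <- 300
  X <- cbind(1, rnorm(n))
  y <- rpois(n, exp(1.5 + 0.1 * X[, 2]))
  f1 <- fit_quasipoisson(X[, 1, drop = FALSE], y)
  f2 <- fit_quasipoisson(X, y)
  # same-sample comparison: qAIC difference decomposes into the Poisson
  # log-likelihood gain and the dispersion-scaled parameter penalty
  expect_equal(compute_qaic(f2) - compute_qaic(f1),
               -2 * (f2$loglik - f1$loglik) +
                 2 * (f2$k * f2$dispersion - f1$k * f1$dispersion),
               tolerance = 1e-10)
  expect_equal(f2$k - f1$k, 1L)
})

test_that("station and reanalysis fits share the same rows after alignment", {
  cfg <- sim_config(n_cities = 1, years = 2, seed = 51)
  ct <- simulate_study(cfg)$cities[[1]]
  ct$data$temp_station[c(100, 300:305)] <- NA
  ct$data$temp_reanalysis[c(200, 500)] <- NA
  ct <- align_city_exposures(ct)
  fs <- fit_city(ct, "station")$fit
  fr <- fit_city(ct, "reanalysis")$fit
  expect_identical(fs$n_obs, fr$n_obs)
  expect_identical(fs$rows_used, fr$rows_used)
  expect_identical(fs$y, fr$y)
})

test_that("pointwise CIs are calibrated when the truth lies in the basis span", {
  # With flat slopes the true curve (identically zero) is exactly
  # representable by the exposure spline, so delta-method 95% CIs must
  # cover it at essentially every grid point.
  covs <- vapply(1:3, function(i) {
    cfg <- sim_config(n_cities = 1, years = 5, heat_slope = 0,
                      cold_slope = 0, seed = 200 + i)
    st <- simulate_study(cfg)
    a <- fit_city(st$cities[[1]], "station")$assoc
    grid <- seq(a$percentiles[["5%"]], a$percentiles[["95%"]],
                length.out = 40)
    pred <- predict_cumulative(a$eta, a$vcov, a$spec, grid,
                               centre = cfg$mmt_true)
    mean(abs(pred$logrr) <= qnorm(0.975) * pred$se)
  }, 0)
  expect_gte(mean(covs), 0.9)
})

test_that("the fitted curve recovers the shape of the V-shaped truth", {
  # The natural cubic spline cannot represent the kink of the true V at
  # the MMT, so pointwise recovery of the kinked truth is biased (the
  # acceptance suite quantifies this).  The qualitative shape, however,
  # must be recovered: risk rises towards both tails, with an interior
  # minimum.  Evidence is pooled across independent replicates.
  zc <- zh <- numeric(4)
  for (s in 61:64) {
    cfg <- sim_config(n_cities = 1, years = 10, seed = s)
    st <- simulate_study(cfg)
    a <- fit_city(st$cities[[1]], "station")$assoc
    p <- a$percentiles
    grid <- seq(p[["1%"]], p[["99%"]], length.out = 60)
    pred <- predict_cumulative(a$eta, a$vcov, a$spec, grid,
                               centre = cfg$mmt_true)
    imin <- which.min(pred$logrr)
    expect_gt(imin, 1L)
    expect_lt(imin, 60L)
    cold <- predict_cumulative(a$eta, a$vcov, a$spec, p[["1%"]],
                               centre = grid[imin])
    heat <- predict_cumulative(a$eta, a$vcov, a$spec, p[["99%"]],
                               centre = grid[imin])
    i <- s - 60
    zc[i] <- cold$logrr / cold$se
    zh[i] <- heat$logrr / heat$se
  }
  # both arms estimated positive in every replicate ...
  expect_true(all(zc > 0))
  expect_true(all(zh > 0))
  # ... and jointly significant across the four independent replicates
  expect_gt(sum(zc) / 2, qnorm(0.975))
  expect_gt(sum(zh) / 2, qnorm(0.975))
})
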
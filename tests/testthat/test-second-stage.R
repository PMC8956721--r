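# Multivariate multilevel meta-regression, BLUPs, heterogeneity.

test_that("fixed-effects limit equals the inverse-variance weighted mean", {
  theta <- c(0.2, -0.1, 0.4, 0.0)
  s2 <- c(0.04, 0.01, 0.09, 0.02)
  md <- scalar_md(theta, s2)
  fit <- fit_meta(md, struct = "fixed")
  expect_equal(unname(fit$B[1, 1]), sum(theta / s2) / sum(1 / s2),
               tolerance = 1e-10)
  expect_equal(unname(fit$vcov_beta[1, 1]), 1 / sum(1 / s2),
               tolerance = 1e-10)
  expect_equal(fit$Psi1, matrix(0, 1, 1))
  expect_equal(fit$Psi2, matrix(0, 1, 1))
})

test_that("duplicating every city leaves the fixed-effect estimate unchanged", {
  theta <- c(0.3, -0.2, 0.1)
  s2 <- c(0.02, 0.05, 0.01)
  f1 <- fit_meta(scalar_md(theta, s2), struct = "fixed")
  f2 <- fit_meta(scalar_md(rep(theta, 2), rep(s2, 2)), struct = "fixed")
  expect_equal(f2$B, f1$B, tolerance = 1e-10)
})

test_that("two-level components and fixed effects are recovered at scale", {
  # 120 cities in 12 groups, p = 2 outcomes, one meta-predictor.
  set.seed(301)
  n <- 120L; p <- 2L
  grp <- rep(sprintf("g%02d", 1:12), each = 10)
  zpred <- rnorm(n)
  B_true <- rbind(c(0.5, -0.3), c(0.2, 0.1))   # rows: intercept, zpred
  Psi2 <- diag(0.04, p); Psi1 <- diag(0.01, p)
  u1 <- matrix(rnorm(12 * p, sd = 0.1), 12, p)   # group effects
  theta <- matrix(NA_real_, n, p)
  S <- vector("list", n)
  for (i in 1:n) {
    S[[i]] <- diag(0.01, p)
    mu <- c(1, zpred[i]) %*% B_true + u1[match(grp[i], unique(grp)), ] +
      MASS::mvrnorm(1, rep(0, p), Psi2)
    theta[i, ] <- MASS::mvrnorm(1, as.numeric(mu), S[[i]])
  }
  assocs <- lapply(1:n, function(i)
    structure(list(eta = theta[i, ], vcov = S[[i]],
                   spec = spline_spec(knots = 1, boundary = c(0, 2)),
                   percentiles = stats::quantile(0:1, 0:100 / 100),
                   range = c(0, 2), city = paste0("c", i),
                   exposure_choice = "station"),
              class = "reduced_assoc"))
  md <- meta_dataset(assocs,
                     data.frame(city = paste0("c", 1:n), country = grp,
                                zone = "z", zpred = zpred),
                     formula = ~zpred)
  fit <- fit_meta(md, struct = "diag")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov_beta))
  # vec(B) stacks outcomes over predictors; compare on the original scale
  expect_true(all(abs(as.numeric(fit$B) - as.numeric(B_true)) < 3 * se))
  # diagonal variance components within 50% relative error
  expect_true(all(abs(diag(fit$Psi2) - 0.04) / 0.04 < 0.5))
  expect_true(all(diag(fit$Psi1) >= 0))
})

test_that("BLUPs reduce to the closed-form scalar shrinkage", {
  zero <- matrix(0, 1, 1)
  # Psi = 0: BLUP equals the pooled mean for every city
  md <- scalar_md(c(0.3, -0.1, 0.2), c(0.02, 0.02, 0.02))
  f0 <- fit_meta(md, struct = "fixed")
  bl0 <- compute_blups(f0)
  for (b in bl0)
    expect_equal(b$eta, unname(f0$B[1, 1]), tolerance = 1e-10)
  # psi/(psi + s) shrinkage with a frozen single-level psi:
  # theta = +/-2, s = psi -> BLUPs are +/-1 around the pooled mean 0
  s <- 0.5
  md2 <- scalar_md(c(2, -2), c(s, s))
  f2 <- fit_meta(md2, psi_fixed = list(Psi1 = zero,
                                       Psi2 = matrix(s, 1, 1)))
  bl2 <- compute_blups(f2)
  expect_equal(bl2[[1]]$eta, 1, tolerance = 1e-10)
  expect_equal(bl2[[2]]$eta, -1, tolerance = 1e-10)
  # general scalar formula against an arbitrary configuration
  theta <- c(0.5, 0.1, -0.3, 0.2); s2 <- c(0.02, 0.08, 0.01, 0.04)
  psi <- 0.03
  f3 <- fit_meta(scalar_md(theta, s2),
                 psi_fixed = list(Psi1 = zero, Psi2 = matrix(psi, 1, 1)))
  mu <- unname(f3$B[1, 1])
  bl3 <- compute_blups(f3)
  for (i in seq_along(theta)) {
    expect_equal(bl3[[i]]$eta, mu + psi / (psi + s2[i]) * (theta[i] - mu),
                 tolerance = 1e-10)
    # conditional variance psi - psi^2/(psi + s) = psi*s/(psi+s), up to
    # the (here ignored) uncertainty in mu: exact because mu is profiled
    # out of neither -- so only check ordering and positivity
    expect_gt(bl3[[i]]$vcov[1, 1], 0)
    expect_lt(bl3[[i]]$vcov[1, 1], psi)
  }
  # near-zero within-city variance: BLUP sticks to theta
  f4 <- fit_meta(scalar_md(c(0.7, -0.4), c(1e-8, 1e-8)),
                 psi_fixed = list(Psi1 = zero,
                                  Psi2 = matrix(0.05, 1, 1)))
  bl4 <- compute_blups(f4)
  expect_equal(bl4[[1]]$eta, 0.7, tolerance = 1e-5)
  expect_equal(bl4[[2]]$eta, -0.4, tolerance = 1e-5)
})

test_that("scalar BLUPs lie between the city estimate and the pooled mean", {
  set.seed(311)
  theta <- rnorm(8, 0.2, 0.3); s2 <- runif(8, 0.01, 0.1)
  md <- scalar_md(theta, s2)
  fit <- fit_meta(md, psi_fixed = list(Psi1 = matrix(0, 1, 1)))
  mu <- unname(fit$B[1, 1])
  bl <- compute_blups(fit)
  for (i in seq_along(theta)) {
    lo <- min(theta[i], mu); hi <- max(theta[i], mu)
    expect_gte(bl[[i]]$eta, lo - 1e-10)
    expect_lte(bl[[i]]$eta, hi + 1e-10)
  }
})

test_that("heterogeneity statistics match hand computation and the null", {
  # identical inputs: Q = 0, I2 = 0
  md0 <- scalar_md(rep(0.25, 5), rep(0.04, 5))
  h0 <- heterogeneity_stats(md0)
  expect_equal(h0$Q, 0, tolerance = 1e-10)
  expect_equal(h0$I2, 0)
  expect_equal(h0$df, 4L)
  # 4-value hand oracle
  theta <- c(0.1, 0.3, -0.2, 0.4); s2 <- c(0.02, 0.05, 0.04, 0.01)
  beta <- sum(theta / s2) / sum(1 / s2)
  Q_hand <- sum((theta - beta)^2 / s2)
  h <- heterogeneity_stats(scalar_md(theta, s2))
  expect_equal(h$Q, Q_hand, tolerance = 1e-10)
  expect_equal(h$p_value, pchisq(Q_hand, 3, lower.tail = FALSE))
  # null calibration: homogeneous replicates give mean Q ~ df
  set.seed(321)
  n <- 6L; reps <- 500L
  Qs <- vapply(seq_len(reps), function(r) {
    s2r <- runif(n, 0.01, 0.05)
    heterogeneity_stats(scalar_md(rnorm(n, 0.2, sqrt(0) + 0) +
                                    rnorm(n, 0, sqrt(s2r)), s2r))$Q
  }, 0)
  df <- n - 1L
  mc_se <- sqrt(2 * df / reps)   # sd of chi-square(df) / sqrt(reps)
  expect_lt(abs(mean(Qs) - df), 3 * mc_se)
})

test_that("scalar two-level fit agrees with metafor::rma.mv", {
  skip_if_not_installed("metafor")
  set.seed(331)
  n <- 40L
  grp <- rep(sprintf("g%d", 1:8), each = 5)
  s2 <- runif(n, 0.01, 0.05)
  theta <- 0.3 + rep(rnorm(8, 0, 0.1), each = 5) + rnorm(n, 0, 0.15) +
    rnorm(n, 0, sqrt(s2))
  md <- scalar_md(theta, s2, group = grp)
  fit <- fit_meta(md)
  dat <- data.frame(yi = theta, grp = grp, city = paste0("c", 1:n))
  rma <- metafor::rma.mv(yi, V = s2, random = ~1 | grp / city,
                         data = dat, method = "REML")
  expect_equal(unname(fit$B[1, 1]), unname(as.numeric(rma$beta)),
               tolerance = 1e-4)
  expect_equal(sqrt(fit$vcov_beta[1, 1]), unname(rma$se),
               tolerance = 1e-4)
  expect_equal(unname(fit$Psi1[1, 1]), rma$sigma2[1], tolerance = 1e-3)
  expect_equal(unname(fit$Psi2[1, 1]), rma$sigma2[2], tolerance = 1e-3)
})

test_that("predictor standardisation does not change the reported effects", {
  set.seed(341)
  n <- 30L
  z <- runif(n, 100, 200)   # badly scaled predictor
  s2 <- runif(n, 0.01, 0.03)
  theta <- 0.2 + 0.004 * z + rnorm(n, 0, 0.1) + rnorm(n, 0, sqrt(s2))
  metadata <- data.frame(city = paste0("c", 1:n), country = "A",
                         zone = "z", z = z)
  assocs <- lapply(1:n, function(i)
    structure(list(eta = theta[i], vcov = matrix(s2[i], 1, 1),
                   spec = spline_spec(boundary = c(0, 1)),
                   percentiles = stats::quantile(0:1, 0:100 / 100),
                   range = c(0, 1), city = paste0("c", i),
                   exposure_choice = "station"),
              class = "reduced_assoc"))
  f_std <- fit_meta(meta_dataset(assocs, metadata, formula = ~z),
                    psi_fixed = list(Psi1 = matrix(0, 1, 1)))
  f_raw <- fit_meta(meta_dataset(assocs, metadata, formula = ~z,
                                 scale_predictors = FALSE),
                    psi_fixed = list(Psi1 = matrix(0, 1, 1)))
  expect_equal(f_std$B, f_raw$B, tolerance = 1e-4)
  # prediction at a covariate profile uses the original scale
  expect_equal(unname(predict(f_std, data.frame(z = 150))),
               unname(f_std$B[1, 1] + 150 * f_std$B[2, 1]),
               tolerance = 1e-10)
})
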
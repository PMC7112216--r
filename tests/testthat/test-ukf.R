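test_that("sigma-point weights match the closed formulas", {
  w <- ukf_weights(4, alpha = 1, beta_w = 2, kappa = 0)
  expect_identical(w$lambda, 0)
  expect_equal(w$w_mean, c(0, rep(0.125, 8)))
  expect_equal(w$w_cov[1], 2)
  expect_equal(w$w_cov[-1], rep(0.125, 8))

  # identities over a parameter sweep
  for (L in c(1, 2, 4, 6)) {
    for (alpha in c(0.3, 1, 1.7)) {
      for (kappa in c(0, 0.5, 3 - L)) {
        lambda <- alpha^2 * (L + kappa) - L
        if (abs(L + lambda) < 1e-9) next
        w <- ukf_weights(L, alpha, beta_w = 2, kappa = kappa)
        expect_equal(sum(w$w_mean), 1, tolerance = 1e-12)
        expect_equal(w$w_cov[1] - w$w_mean[1], 1 - alpha^2 + 2, tolerance = 1e-12)
        expect_equal(w$w_mean[-1], rep(1 / (2 * (L + lambda)), 2 * L))
      }
    }
  }
  # beta_w = 0 makes the first covariance and mean weights coincide
  w0 <- ukf_weights(4, alpha = 1, beta_w = 0, kappa = 0)
  expect_equal(w0$w_cov[1], w0$w_mean[1])
  # degenerate spread rejected
  expect_error(ukf_weights(2, alpha = 1, kappa = -2), "degenerate")
})

test_that("sigma points encode the mean and covariance they were drawn from", {
  w <- ukf_weights(4)
  sig <- sigma_points(rep(0, 4), diag(4), w)
  expect_identical(dim(sig$points), c(4L, 9L))
  # identity covariance, lambda = 0: offsets are +-2 unit vectors
  expect_equal(sig$points[, 2:5], 2 * diag(4))
  expect_equal(sig$points[, 6:9], -2 * diag(4))

  m <- c(10, 4, 0.5, -1)
  P <- crossprod(matrix(c(2, 0.3, 0, 0.1,
                          0, 1.5, 0.2, 0,
                          0, 0, 0.8, 0.05,
                          0, 0, 0, 0.6), 4, 4, byrow = TRUE))
  sig <- sigma_points(m, P, w)
  # weighted mean reproduces the input mean
  expect_equal(drop(sig$points %*% sig$w_mean), m, tolerance = 1e-12)
  # weighted covariance reproduces the input covariance (brute force)
  d <- sig$points - m
  recon <- matrix(0, 4, 4)
  for (j in 1:9)
    recon <- recon + sig$w_cov[j] * d[, j] %*% t(d[, j])
  expect_equal(recon, P, tolerance = 1e-10)
})

test_that("the unscented transform is exact for linear maps of Gaussian sets", {
  set.seed(3)
  w <- ukf_weights(4)
  m <- c(50, 20, 0.01, 0.2)
  P <- diag(c(4, 3, 1e-4, 1e-3))
  A <- matrix(rnorm(16, sd = 0.5), 4, 4)
  b <- c(1, -2, 0.5, 0)
  sig <- sigma_points(m, P, w)
  y <- A %*% sig$points + b
  ym <- drop(y %*% sig$w_mean)
  d <- y - ym
  yc <- matrix(0, 4, 4)
  for (j in 1:9) yc <- yc + sig$w_cov[j] * d[, j] %*% t(d[, j])
  expect_equal(ym, drop(A %*% m + b), tolerance = 1e-10)
  expect_equal(yc, A %*% P %*% t(A), tolerance = 1e-10)
})

test_that("the time update matches a dense recomputation of the weighted moments", {
  w <- ukf_weights(4)
  m <- c(60, 30, 0.01, 0.2)
  P <- diag(c(2, 2, 1e-3, 1e-3))
  dt <- 0.25
  q <- c(10, 10, 100, 100)
  sig <- sigma_points(m, P, w)
  prior <- ukf_predict(sig, dt, q)

  # independent dense recomputation: propagate each column by hand
  pts <- sig$points
  prop <- matrix(NA_real_, 4, 9)
  for (j in 1:9) {
    x <- pts[, j]
    prop[, j] <- c(x[1] - x[3] * x[1] * x[2] * dt,
                   x[2] + (x[3] * x[1] * x[2] - x[4] * x[2]) * dt,
                   x[3], x[4])
  }
  mm <- drop(prop %*% sig$w_mean)
  PP <- diag(q)
  for (j in 1:9)
    PP <- PP + sig$w_cov[j] * (prop[, j] - mm) %*% t(prop[, j] - mm)
  expect_equal(prior$mean, mm, tolerance = 1e-10)
  expect_equal(prior$cov, (PP + t(PP)) / 2, tolerance = 1e-10)

  # all points identical: prior covariance collapses to Q
  const <- structure(list(points = matrix(m, 4, 9), w_mean = w$w_mean,
                          w_cov = w$w_cov, lambda = w$lambda),
                     class = "sigma_set")
  expect_equal(ukf_predict(const, dt, q)$cov, diag(q), tolerance = 1e-12)

  # beta components zero in every point: S is untouched by propagation
  m0 <- c(60, 30, 0, 0.2)
  off <- 2 * diag(c(1, 1, 0, 0))  # spread only in the S, I directions
  sig0 <- structure(list(points = cbind(m0, m0 + off, m0 - off,
                                        deparse.level = 0),
                         w_mean = w$w_mean, w_cov = w$w_cov,
                         lambda = w$lambda),
                    class = "sigma_set")
  prior0 <- ukf_predict(sig0, dt)
  expect_identical(prior0$points[1, ], sig0$points[1, ])
})

test_that("the measurement update reduces to the classical Kalman formulas", {
  # scalar case: posterior = prior + P/(P+R) * innovation
  w1 <- ukf_weights(1, alpha = 1, beta_w = 0, kappa = 2)
  m <- 5; P <- 4; R <- 2; y <- 7
  sig <- sigma_points(m, matrix(P), w1)
  prior <- list(mean = m, cov = matrix(P), points = sig$points,
                w_mean = sig$w_mean, w_cov = sig$w_cov)
  post <- ukf_update(prior, y, R)
  expect_equal(post$mean, m + P / (P + R) * (y - m), tolerance = 1e-12)
  expect_equal(post$cov[1, 1], P - P^2 / (P + R), tolerance = 1e-12)

  # zero innovation: posterior mean = prior mean
  w <- ukf_weights(4)
  m4 <- c(60, 30, 0.01, 0.2)
  sig4 <- sigma_points(m4, diag(c(2, 2, 1e-3, 1e-3)), w)
  prior4 <- ukf_predict(sig4, 0.25, c(1, 1, 1, 1))
  ypred <- drop(prior4$points[1:2, ] %*% prior4$w_mean)
  post4 <- ukf_update(prior4, ypred, c(10, 10))
  expect_equal(post4$mean, prior4$mean, tolerance = 1e-10)

  # R -> infinity: observation carries no information
  postR <- ukf_update(prior4, c(0, 100), c(1e12, 1e12))
  expect_equal(postR$mean, prior4$mean, tolerance = 1e-6)
  expect_equal(postR$cov, prior4$cov, tolerance = 1e-6)

  # informative observation shrinks the covariance trace
  postI <- ukf_update(prior4, ypred + c(1, -1), c(0.1, 0.1))
  expect_lt(sum(diag(postI$cov)), sum(diag(prior4$cov)))
})

test_that("the filter runs one posterior per observation and stays symmetric", {
  s <- city_fixture("fort-myers-naples", noise_sd = 2, seed = 5)
  expect_identical(nrow(s), 49L)  # 12 days at 0.25-day steps + initial
  est <- run_ukf(s, ukf_settings(dt = 0.25))
  expect_identical(nrow(est$mean), 49L)
  for (k in c(2L, 25L, 49L)) {
    P <- est$cov[, , k]
    expect_lt(max(abs(P - t(P))), 1e-10)
  }
  expect_equal(est$mean[1, c("s_hat", "i_hat")],
               c(s_hat = s$s_pct[1], i_hat = s$i_pct[1]))

  # non-uniform series rejected
  bad <- s
  bad$time_days[5] <- bad$time_days[5] + 0.01
  expect_error(run_ukf(bad, ukf_settings(dt = 0.25)), "uniform")
})

test_that("with no infections the transmission rate stays unidentified at zero", {
  ser <- observation_series(seq(0, 5, 0.25), rep(50, 21), rep(0, 21))
  est <- run_ukf(ser, ukf_settings(dt = 0.25))
  expect_true(all(est$mean[, "beta_hat"] == 0))
  expect_true(all(abs(est$mean[, "s_hat"] - 50) < 1e-8))
})

test_that("a noise-free series pins the rate trajectories near the truth", {
  # tight parameter process noise for tracking (defaults favour the refit step)
  spec <- scenario_spec(ftm_params(), ftm_init(), irma_grid(), noise_sd = 0)
  ser <- generate_series(spec)
  est <- run_ukf(ser, ukf_settings(dt = 0.25, q_diag = c(1, 1, 1e-5, 1e-5),
                                   r_diag = c(1, 1)))
  last_third <- seq(ceiling(2 * nrow(est$mean) / 3), nrow(est$mean))
  expect_true(all(abs(est$mean[last_third, "beta_hat"] - 0.0089) / 0.0089 < 0.15))
  expect_true(all(abs(est$mean[last_third, "gamma_hat"] - 0.1901) / 0.1901 < 0.15))
})

test_that("MSE selection matches a brute-force double loop and finds a planted truth", {
  # planted truth: series generated by the constant pair placed in the set
  spec <- scenario_spec(ftm_params(), ftm_init(), irma_grid(), noise_sd = 0)
  ser <- generate_series(spec)
  betas <- c(0.005, 0.007, 0.0089, 0.011, 0.02)
  gammas <- c(0.1, 0.15, 0.1901, 0.25, 0.3)
  fake <- structure(list(mean = cbind(s_hat = rep(60, 5), i_hat = rep(30, 5),
                                      beta_hat = betas, gamma_hat = gammas),
                         times = ser$time_days[1:5]),
                    class = "ukf_estimate")
  fit <- select_constant_parameters(fake, ser)
  expect_equal(fit$beta, 0.0089)
  expect_equal(fit$gamma, 0.1901)
  expect_lt(fit$mse, 1e-12)
  expect_equal(fit$r0, 0.0089 * ser$s_pct[1] / 0.1901)

  # brute-force oracle over the same 5 x 5 candidate set, noisy series
  nser <- generate_series(scenario_spec(ftm_params(), ftm_init(), irma_grid(),
                                        noise_sd = 2, seed = 9))
  nfit <- select_constant_parameters(fake, nser)
  best <- c(Inf, NA, NA)
  for (g in sort(gammas)) {
    for (b in sort(betas)) {
      sim <- oracle_euler(b, g, nser$s_pct[1], nser$i_pct[1], 0, 0.25, 48)
      mse <- mean((sim$i[-1] - nser$i_pct[-1])^2)
      if (mse < best[1] - 1e-15) best <- c(mse, b, g)
    }
  }
  expect_equal(nfit$beta, best[2])
  expect_equal(nfit$gamma, best[3])
  expect_equal(nfit$mse, best[1], tolerance = 1e-10)

  # all-negative candidates abort
  neg <- fake
  neg$mean[, "beta_hat"] <- -1
  expect_error(select_constant_parameters(neg, ser), "empty candidate")
})

test_that("filter plus MSE selection recovers the planted rates from noisy series", {
  # seeded recovery at the registry magnitudes, observation noise sd 2
  errs <- sapply(1:20, function(seed) {
    ser <- city_fixture("fort-myers-naples", noise_sd = 2, seed = seed)
    est <- run_ukf(ser, ukf_settings(dt = 0.25))
    fit <- select_constant_parameters(est, ser)
    c(abs(fit$beta - 0.0089) / 0.0089, abs(fit$gamma - 0.1901) / 0.1901)
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)

  # recovered reproduction number lands near the registry value
  ser <- city_fixture("fort-myers-naples", noise_sd = 2, seed = 1)
  est <- run_ukf(ser, ukf_settings(dt = 0.25))
  fit <- select_constant_parameters(est, ser)
  expect_lt(abs(fit$r0 - 2.90) / 2.90, 0.15)
})
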
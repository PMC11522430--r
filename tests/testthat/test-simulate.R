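test_that("memory-path simulation is seed-reproducible with zero-mean paths", {
  p <- memory_params(0.8, 0.5)
  a <- simulate_memory_paths(p, n_times = 32, n_paths = 500, seed = 4)
  b <- simulate_memory_paths(p, n_times = 32, n_paths = 500, seed = 4)
  c <- simulate_memory_paths(p, n_times = 32, n_paths = 500, seed = 5)
  expect_identical(a$paths, b$paths)
  expect_false(identical(a$paths, c$paths))
  expect_identical(a$time[1], 0)
  expect_true(all(a$paths[, 1] == 0))
  # ensemble mean of x(T) - x_0 within 3 standard errors of 0 everywhere
  mns <- colMeans(a$paths[, -1])
  se <- apply(a$paths[, -1], 2, sd) / sqrt(500)
  expect_true(all(abs(mns) <= 3 * se))
})

test_that("Monte Carlo variance matches the closed-form MSD", {
  p <- memory_params(0.8, 0.5)
  n_paths <- 4000
  ens <- simulate_memory_paths(p, n_times = 64, n_paths = n_paths, seed = 21)
  v <- apply(ens$paths, 2, var)[-1]
  th <- msd_closed_form(p, ens$time[-1])
  se <- th * sqrt(2 / n_paths)       # SE of a Gaussian sample variance
  expect_gte(mean(abs(v - th) <= 3 * se), 0.95)
})

test_that("simulated endpoints are Gaussian", {
  p <- memory_params(0.94, 0.67)
  ens <- simulate_memory_paths(p, n_times = 16, n_paths = 3000, seed = 8)
  xT <- ens$paths[, ncol(ens$paths)]
  expect_gt(stats::shapiro.test(xT)$p.value, 0.01)
})

test_that("simulator rejects out-of-domain horizons and bad counts", {
  p <- memory_params(0.8, 0.5)
  expect_error(simulate_memory_paths(p, T_max = pi / 0.5 + 1, seed = 1),
               "pi/nu")
  expect_error(simulate_memory_paths(p, n_times = 4, seed = 1), "n_times")
  expect_error(simulate_memory_paths(p, n_paths = 0, seed = 1), "n_paths")
})

test_that("fBm generates across the Hurst range with correct scaling", {
  for (H in c(0.1, 0.3, 0.5, 0.7, 0.9))
    expect_s3_class(simulate_fbm(H, n = 4096, n_paths = 1, seed = 3),
                    "path_ensemble")
  # ensemble MSD scaling exponent 2H from 200 paths, lags 1..64
  for (H in c(0.3, 0.5, 0.7)) {
    ens <- simulate_fbm(H, n = 4096, n_paths = 200, seed = 50 + 10 * H)
    X <- ens$paths[, -1]
    taus <- 2^(0:6)
    m <- vapply(taus, function(k)
      mean((X[, (k + 1):4096] - X[, 1:(4096 - k)])^2), numeric(1))
    slope <- unname(coef(lm(log(m) ~ log(taus)))[2])
    expect_lt(abs(slope - 2 * H), 0.05)
  }
})

test_that("H = 0.5 reduces to memoryless Brownian motion", {
  ens <- simulate_fbm(0.5, n = 2048, n_paths = 50, seed = 9)
  inc <- t(apply(ens$paths, 1, diff))
  r1 <- vapply(seq_len(50), function(i)
    cor(inc[i, -1], inc[i, -2048]), numeric(1))
  # pooled lag-1 autocorrelation of increments, SE ~ 1/sqrt(n*paths)
  expect_lt(abs(mean(r1)), 3 / sqrt(2047 * 50))
  a <- simulate_fbm(0.5, n = 128, n_paths = 3, seed = 1)
  b <- simulate_fbm(0.5, n = 128, n_paths = 3, seed = 1)
  expect_identical(a$paths, b$paths)
})

test_that("observable-series generator exposes its ground truth", {
  # zero noise amplitude: the series is exactly the trend
  ts0 <- make_observable_series("linear", list(a = 2, b = 0.1),
                                "memory_process",
                                list(mu = 0.8, nu = 0.5, amplitude = 0),
                                n = 64, seed = 1)
  expect_equal(ts0$values, 2 + 0.1 * ts0$times)
  # linear trend + memory noise: linear detrending recovers the noise up
  # to the OLS projection of the noise itself (exact algebra: the fitted
  # line absorbs the trend plus the noise's own drift component)
  ts1 <- make_observable_series("linear", list(a = 0, b = 0.3),
                                "memory_process",
                                list(mu = 0.8, nu = 0.5, amplitude = 1),
                                n = 144, seed = 2)
  truth <- attr(ts1, "truth")
  fl <- linear_detrend(ts1)
  noise_detr <- linear_detrend(eco_ts(truth$noise, times = ts1$times))
  expect_equal(fl$residuals, noise_detr$residuals, tolerance = 1e-10)
  expect_equal(cor(fl$residuals, noise_detr$residuals), 1)
  # seasonal + fBm: spectral detrending strips the seasonal component
  ts2 <- make_observable_series(
    "seasonal_linear",
    list(a = 0, b = 0.02, c = 3, period = 12, phase = 0.4),
    "fbm", list(H = 0.7, amplitude = 0.5), n = 240, seed = 3)
  s <- attr(ts2, "truth")$trend - (0.02 * ts2$times) - 0  # seasonal part
  s <- s - mean(s)
  fl2 <- fourier_detrend(ts2)
  leak <- sum(fl2$residuals * s) / sum(s * s)  # seasonal left in residuals
  expect_lt(leak^2, 0.05)                      # >= 95% of variance removed
})
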
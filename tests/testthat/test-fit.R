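test_that("noiseless model curves are recovered exactly", {
  # truth on a rescaled axis: t_c = 2, N = 3; the reporting convention
  # fixed at the true t_c makes all four parameters identifiable
  tau <- seq(0.25, 9, length.out = 40)
  cv <- model_curve(0.9, 0.6, t_c = 2, N = 3, lags = tau)
  f <- fit_msd(cv, n_bootstrap = 0, seed = 1, t_c = 2)
  expect_lt(abs(f$params$mu - 0.9) / 0.9, 1e-3)
  expect_lt(abs(f$params$nu - 0.6) / 0.6, 1e-3)
  expect_lt(abs(f$scaling$N - 3) / 3, 1e-3)
  expect_gt(f$r2, 1 - 1e-8)
  expect_true(f$converged)
  # without knowledge of t_c the identifiable pair is still recovered:
  # omega = nu/t_c and amplitude A = N * t_c^(1 - 2 mu)
  f1 <- fit_msd(cv, n_bootstrap = 0, seed = 1)
  expect_lt(abs(f1$omega - 0.3) / 0.3, 1e-3)
  expect_lt(abs(f1$amplitude - 3 * 2^(1 - 1.8)) / (3 * 2^(1 - 1.8)), 1e-3)
  expect_lt(abs(f1$params$mu - 0.9) / 0.9, 1e-3)
})

test_that("noiseless identifiability across a grid of truths", {
  for (mu in c(0.6, 0.9, 1.2)) {
    for (nu in c(0.35, 0.62, 1.0)) {
      tau <- seq(0.05, 0.95, length.out = 24) * pi / nu
      cv <- model_curve(mu, nu, t_c = 1, N = 2.5, lags = tau)
      f <- fit_msd(cv, n_bootstrap = 0, seed = 1, t_c = 1)
      expect_lt(abs(f$params$mu - mu) / mu, 1e-3)
      expect_lt(abs(f$params$nu - nu) / nu, 1e-3)
      expect_equal(f$scaling$t_c, 1)
      expect_lt(abs(f$scaling$N - 2.5) / 2.5, 1e-3)
    }
  }
})

test_that("fit is equivariant under amplitude and time-unit rescaling", {
  tau <- seq(0.3, 7, length.out = 30)
  cv <- model_curve(0.8, 0.55, t_c = 1.5, N = 1.7, lags = tau)
  f <- fit_msd(cv, n_bootstrap = 0, seed = 1)
  cv2 <- cv; cv2$msd <- 10 * cv$msd
  f2 <- fit_msd(cv2, n_bootstrap = 0, seed = 1)
  expect_equal(f2$params$mu, f$params$mu, tolerance = 1e-6)
  expect_equal(f2$params$nu, f$params$nu, tolerance = 1e-6)
  expect_equal(f2$scaling$N / f$scaling$N, 10, tolerance = 1e-6)
  # relabeling the lag axis (e.g. months -> weeks) rescales nu, not mu
  cv3 <- cv; cv3$lags <- cv$lags * 4; cv3$time_unit <- "week"
  f3 <- fit_msd(cv3, n_bootstrap = 0, seed = 1)
  expect_equal(f3$params$mu, f$params$mu, tolerance = 1e-6)
  expect_equal(f3$params$nu, f$params$nu / 4, tolerance = 1e-6)
})

test_that("a short-lag pure power law maps to mu = beta/2", {
  tau <- seq(0.01, 0.4, length.out = 25)
  cv <- structure(list(lags = tau, msd = 2 * tau^1.4,
                       n_pairs = rep(50L, 25), source = "empirical",
                       dt = tau[1], time_unit = "month"),
                  class = "msd_curve")
  f <- fit_msd(cv, n_bootstrap = 0, seed = 1)
  expect_lt(abs(f$params$mu - 0.7), 0.02)
})

test_that("bootstrap intervals are percentile-based, seeded, and sane", {
  p <- memory_params(0.8, 0.5)
  ens <- simulate_memory_paths(p, n_times = 48, n_paths = 400, seed = 61)
  emp <- msd_ensemble(ens)
  f <- fit_msd(emp, n_bootstrap = 100, seed = 7)
  g <- fit_msd(emp, n_bootstrap = 100, seed = 7)
  expect_identical(f$ci95, g$ci95)
  expect_true(all(f$ci95[, "lower"] <= f$ci95[, "upper"]))
  expect_gte(f$params$mu, f$ci95["mu", "lower"])
  expect_lte(f$params$mu, f$ci95["mu", "upper"])
  rep <- report(f)
  expect_equal(rep$mu_ci_half, unname(diff(f$ci95["mu", ])) / 2)
  expect_equal(rep$beta, 2 * f$params$mu)
})

test_that("report carries the superdiffusion classification", {
  tau <- seq(0.25, 4.5, length.out = 24)
  cv <- model_curve(0.94, 0.67, lags = tau)
  f <- fit_msd(cv, n_bootstrap = 0, seed = 1)
  r <- report(f)
  expect_equal(r$beta, 1.88, tolerance = 1e-3)
  expect_equal(r$regime, "superdiffusive")
  cvd <- model_curve(0.5, 0.67, lags = tau)
  rd <- report(fit_msd(cvd, n_bootstrap = 0, seed = 1))
  expect_equal(rd$beta, 1, tolerance = 1e-3)
})

test_that("degenerate fit inputs are rejected with guidance", {
  cv <- model_curve(0.9, 0.6, lags = seq(0.5, 4.5, length.out = 6))
  expect_error(fit_msd(cv, n_bootstrap = 0, seed = 1), "8 lag")
  cv2 <- model_curve(0.9, 0.6, lags = seq(0.3, 4.5, length.out = 12))
  expect_error(fit_msd(cv2, bounds = list(nu = c(4, 5)), n_bootstrap = 0,
                       seed = 1), "admissible")
})

test_that("bootstrap confidence intervals cover the true memory parameter", {
  # replicates with independent per-lag errors: the sampling model the
  # residual bootstrap targets (MSD curves whose errors are correlated
  # across lags undercover; see the vignette)
  p <- memory_params(0.8, 0.5)
  tau <- seq(0.15, 0.95, length.out = 32) * pi / 0.5
  m_true <- 2 * msd_closed_form(p, tau)
  sigma <- 0.08 * mean(m_true)
  covered <- withr::with_seed(424242, vapply(1:100, function(i) {
    cv <- structure(list(lags = tau, msd = m_true + rnorm(32, 0, sigma),
                         n_pairs = rep(100L, 32), source = "empirical",
                         dt = tau[1], time_unit = "month"),
                    class = "msd_curve")
    f <- fit_msd(cv, n_bootstrap = 150, seed = 2000 + i)
    f$ci95["mu", "lower"] <= 0.8 && 0.8 <= f$ci95["mu", "upper"]
  }, logical(1)))
  expect_gte(sum(covered), 85)
})
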
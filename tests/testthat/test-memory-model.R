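test_that("closed-form MSD matches the isometry quadrature across the grid", {
  for (mu in c(0.3, 0.5, 0.68, 0.78, 0.94, 1.2)) {
    for (nu in c(0.3, 0.66, 1.0)) {
      p <- memory_params(mu, nu)
      T <- seq(pi / nu / 10, pi / nu, length.out = 10)
      cf <- msd_closed_form(p, T)
      q <- msd_quadrature(p, T)
      expect_lt(max(abs(cf - q) / abs(q)), 1e-6)
      expect_true(all(cf > 0))              # strictly positive on (0, pi/nu)
    }
  }
})

test_that("MSD vanishes at T = 0 and errors outside the process domain", {
  p <- memory_params(0.78, 0.66)
  expect_identical(msd_closed_form(p, 0), 0)
  expect_error(msd_closed_form(p, pi / 0.66 + 0.1), "pi/nu")
  expect_error(msd_closed_form(p, -1), "domain")
  expect_error(msd_quadrature(p, 0), "domain")
  expect_error(memory_params(-0.5, 1), "mu")
  expect_error(memory_params(0.5, 0), "nu")
})

test_that("quadrature reduces to the elementary integral at mu = 1", {
  for (nu in c(0.3, 0.7, 1.5)) {
    p <- memory_params(1, nu)
    T <- pi / nu * c(0.25, 0.6, 1)
    expect_equal(msd_quadrature(p, T), (1 - cos(nu * T)) / nu,
                 tolerance = 1e-9)
  }
  # endpoint stress case: agreement holds at the very edge of the domain
  p <- memory_params(0.78, 0.66)
  Tend <- pi / 0.66
  expect_equal(msd_quadrature(p, Tend), msd_closed_form(p, Tend),
               tolerance = 1e-6)
})

test_that("short-time power law: coefficient, asymptotic ratio, slope", {
  # mu = 1/2, nu = 1: b = sqrt(pi)*Gamma(1/2)/(2*Gamma(1)) = pi/2, beta = 1
  p <- memory_params(0.5, 1)
  expect_equal(msd_short_time(p, 1), pi / 2, tolerance = 1e-12)
  expect_identical(msd_short_time(p, 0), 0)
  for (mu in c(0.3, 0.5, 0.68, 0.78, 0.94, 1.2)) {
    p <- memory_params(mu, 1.0)
    # ratio -> 1 monotonically as T -> 0 (Bessel branch, nu*T >= 1e-6)
    Ts <- 10^seq(-1, -5, by = -1)
    ratio <- msd_short_time(p, Ts) / msd_closed_form(p, Ts)
    expect_lt(abs(ratio[length(Ts)] - 1), 1e-3)
    expect_true(all(diff(abs(ratio - 1)) < 0))
    # local log-log slope at short times equals beta = 2*mu
    expect_equal(loglog_slope(p, 1e-6, 1e-4), 2 * mu, tolerance = 1e-2)
  }
})

test_that("beta exponent and diffusion-regime classification", {
  expect_equal(beta_exponent(memory_params(0.5, 1)),
               list(beta = 1, regime = "diffusive"))
  expect_equal(beta_exponent(table1_params$gnee)$beta, 1.88)
  expect_equal(beta_exponent(table1_params$gnee)$regime, "superdiffusive")
  expect_equal(beta_exponent(table1_params$gsst)$beta, 1.36)
  expect_equal(beta_exponent(memory_params(0.3, 1))$regime, "subdiffusive")
  expect_equal(beta_exponent(memory_params(1.2, 1))$regime, "beta >= 2")
})

test_that("endpoint density: normalization, variance, symmetry, typo form", {
  cases <- list(c(0.78, 0.66, 3), c(0.94, 0.67, 2), c(0.68, 0.30, 5))
  for (cs in cases) {
    p <- memory_params(cs[1], cs[2])
    T <- cs[3]
    s2 <- msd_closed_form(p, T)
    lim <- 12 * sqrt(s2)
    Z <- integrate(function(x) memory_pdf(x, 0, p, T), -lim, lim,
                   rel.tol = 1e-12)$value
    expect_equal(Z, 1, tolerance = 1e-8)
    m2 <- integrate(function(x) x^2 * memory_pdf(x, 0, p, T), -lim, lim,
                    rel.tol = 1e-12)$value
    expect_equal(m2, s2, tolerance = 1e-8)
    d <- 1.3
    expect_equal(memory_pdf(2 + d, 2, p, T), memory_pdf(2 - d, 2, p, T))
    Zp <- integrate(function(x) memory_pdf(x, 0, p, T, "as_printed"),
                    -lim, lim, rel.tol = 1e-12)$value
    expect_equal(Zp, sqrt(pi), tolerance = 1e-8)
  }
  expect_error(memory_pdf(0, 0, memory_params(0.8, 1), T = 4), "domain")
})

test_that("scaled MSD: identity, linearity in N, reported lag limit", {
  p <- memory_params(0.94, 0.67)
  t <- seq(0.3, 4.5, by = 0.3)
  expect_equal(scaled_msd(p, fit_scaling(1, 1), t), msd_closed_form(p, t))
  s <- fit_scaling(t_c = 1.273, N = 2.629)
  expect_equal(scaled_msd(p, s, 1), 2.629 * msd_closed_form(p, 1 / 1.273))
  s2 <- fit_scaling(t_c = 1.273, N = 2 * 2.629)
  expect_equal(scaled_msd(p, s2, t[t < 5]), 2 * scaled_msd(p, s, t[t < 5]))
  expect_error(scaled_msd(p, s, 100), "t_c\\*pi/nu")
})
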
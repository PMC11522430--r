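# Fitted parameter sets for the three systems (monthly NEE flux, weekly
# CO2, monthly SST anomaly) and small fixture builders used across tests.

table1 <- list(
  gnee = list(mu = 0.94, nu = 0.67, unit = "month"),
  co2  = list(mu = 0.78, nu = 0.66, unit = "week"),
  gsst = list(mu = 0.68, nu = 0.30, unit = "month"))

table1_params <- lapply(table1, function(p)
  memory_params(p$mu, p$nu, p$unit))

# exact model curve N * MSD(mu, nu, tau/t_c) wrapped as an msd_curve
model_curve <- function(mu, nu, t_c = 1, N = 1, lags) {
  p <- memory_params(mu, nu)
  structure(list(lags = lags,
                 msd = N * msd_closed_form(p, lags / t_c),
                 n_pairs = rep(100L, length(lags)),
                 source = "empirical", dt = lags[1],
                 time_unit = "month"),
            class = "msd_curve")
}

# log-log slope of an MSD curve over a time window
loglog_slope <- function(params, lo, hi, n = 20) {
  T <- exp(seq(log(lo), log(hi), length.out = n))
  m <- msd_closed_form(params, T)
  unname(coef(stats::lm(log(m) ~ log(T)))[2])
}
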
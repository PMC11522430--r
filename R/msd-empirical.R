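#' Empirical or model MSD curve
#'
#' Lags with mean-square-displacement estimates and the number of
#' displacement pairs behind each estimate.
#'
#' @keywords internal
msd_curve <- function(lags, msd, n_pairs, source = c("empirical", "model"),
                      dt = NULL, time_unit = "month") {
  source <- match.arg(source)
  stopifnot(length(lags) == length(msd), length(msd) == length(n_pairs),
            all(diff(lags) > 0), all(lags > 0), all(msd >= -1e-300))
  structure(list(lags = as.numeric(lags), msd = as.numeric(msd),
                 n_pairs = as.integer(n_pairs), source = source,
                 dt = dt, time_unit = time_unit),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s): %d lags in [%g, %g] %ss, msd in [%g, %g]\n",
              x$source, length(x$lags), min(x$lags), max(x$lags),
              x$time_unit, min(x$msd), max(x$msd)))
  invisible(x)
}

#' @export
as.data.frame.msd_curve <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(lag = x$lags, msd = x$msd, n_pairs = x$n_pairs)
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  graphics::plot(x$lags, x$msd, log = log, type = "b",
                 xlab = sprintf("lag (%s)", x$time_unit),
                 ylab = "MSD", ...)
  invisible(x)
}

#' Time-averaged MSD of a single fluctuation series
#'
#' The standard single-trajectory estimator of anomalous-diffusion work:
#' for each lag \eqn{\tau = k\,\Delta t},
#' \deqn{\mathrm{MSD}(\tau) = \frac{1}{n-k}\sum_{t}
#'   \left(x(t+\tau) - x(t)\right)^2,}
#' using all overlapping pairs.  With `anchored = TRUE` the displacement
#' is measured from the first point only,
#' \eqn{(x(\tau) - x(0))^2} (one pair per lag) — a sensitivity check for
#' the alternative reading of an empirical MSD.
#'
#' Note that for a non-stationary process the time-averaged estimator is
#' not the ensemble variance at lag \eqn{\tau}; see the package vignette
#' for what this implies when fitting the theoretical MSD.
#'
#' @param fluct A `"fluctuation_series"` (or [eco_ts()], whose values are
#'   then used directly).
#' @param max_lag_fraction Largest lag as a fraction of the series
#'   length, in (0, 0.5]; default 0.25 keeps >= 75% of pairs per lag.
#' @param anchored Use the anchored single-pair displacement instead of
#'   the overlapping time average.
#' @return An `"msd_curve"` (source `"empirical"`).
#' @examples
#' fl <- linear_detrend(eco_ts(cumsum(rnorm(128))))
#' msd_time_averaged(fl)
#' @export
msd_time_averaged <- function(fluct, max_lag_fraction = 0.25,
                              anchored = FALSE) {
  x <- if (inherits(fluct, "fluctuation_series")) fluct$residuals
       else if (inherits(fluct, "eco_ts")) fluct$values
       else stop("'fluct' must be a fluctuation_series or eco_ts",
                 call. = FALSE)
  dt <- fluct$dt
  n <- length(x)
  if (n < 8) stop("series too short (n < 8) for MSD estimation",
                  call. = FALSE)
  if (max_lag_fraction <= 0 || max_lag_fraction > 0.5)
    stop("'max_lag_fraction' must be in (0, 0.5]", call. = FALSE)
  kmax <- floor(n * max_lag_fraction)
  if (kmax < 1) stop("no admissible lag: series too short for this ",
                     "'max_lag_fraction'", call. = FALSE)
  ks <- seq_len(kmax)
  if (anchored) {
    m <- (x[1 + ks] - x[1])^2
    np <- rep(1L, kmax)
  } else {
    m <- vapply(ks, function(k) mean((x[(k + 1):n] - x[1:(n - k)])^2),
                numeric(1))
    np <- n - ks
  }
  msd_curve(ks * dt, m, np, "empirical", dt = dt,
            time_unit = fluct$time_unit)
}

#' Ensemble MSD of simulated paths
#'
#' Across-path sample variance of the displacement \eqn{x(T_j) - x_0} at
#' each positive grid time — the Monte Carlo counterpart of the
#' closed-form ensemble MSD, used to validate the simulator.
#'
#' @param paths A `"path_ensemble"` with at least 2 paths (for a single
#'   path use [msd_time_averaged()]).
#' @return An `"msd_curve"` (source `"empirical"`, `n_pairs = n_paths`).
#' @examples
#' p <- memory_params(0.8, 0.5)
#' ens <- simulate_memory_paths(p, n_times = 32, n_paths = 200, seed = 2)
#' msd_ensemble(ens)
#' @export
msd_ensemble <- function(paths) {
  stopifnot(inherits(paths, "path_ensemble"))
  if (nrow(paths$paths) < 2)
    stop("ensemble MSD needs >= 2 paths; use msd_time_averaged() for a ",
         "single trajectory", call. = FALSE)
  v <- apply(paths$paths, 2, stats::var)
  keep <- paths$time > 0
  dt <- paths$time[2] - paths$time[1]
  tu <- if (inherits(paths$params_truth, "memory_params"))
    paths$params_truth$time_unit else "time"
  msd_curve(paths$time[keep], v[keep],
            rep(nrow(paths$paths), sum(keep)), "empirical",
            dt = dt, time_unit = tu)
}
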
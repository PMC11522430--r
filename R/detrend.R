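#' Regularly sampled observable series
#'
#' Light container for a univariate, equally spaced time series: the raw
#' input of the pipeline (e.g. monthly sea surface temperature anomalies,
#' weekly CO2 concentrations, monthly carbon fluxes).
#'
#' @param values Numeric observable values; `NA` gaps of at most 2
#'   consecutive points are linearly interpolated with a warning, longer
#'   gaps are an error (the spectral and lag estimators require a
#'   complete regular grid).
#' @param times Optional numeric times; must be strictly increasing and
#'   equally spaced.  Default `0, dt, 2*dt, ...`.
#' @param dt Time step used when `times` is not given.
#' @param time_unit Unit label for the time axis (`"month"`, `"week"`, ...).
#' @param label Free-text source tag.
#' @return An object of class `"eco_ts"`.
#' @examples
#' eco_ts(sin(1:48 / 3), time_unit = "month", label = "demo")
#' @export
eco_ts <- function(values, times = NULL, dt = 1, time_unit = "month",
                   label = "") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (is.null(times)) times <- (seq_len(n) - 1) * dt
  times <- as.numeric(times)
  if (length(times) != n)
    stop("'times' and 'values' lengths differ", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (diff(range(d)) > 1e-8 * mean(d))
    stop("'times' must be equally spaced", call. = FALSE)
  if (anyNA(values)) {
    r <- rle(is.na(values))
    if (any(r$values & r$lengths > 2) || is.na(values[1]) || is.na(values[n]))
      stop("missing-value gaps longer than 2 consecutive interior points",
           call. = FALSE)
    warning("interpolating ", sum(is.na(values)),
            " missing value(s) linearly", call. = FALSE)
    values <- stats::approx(times[!is.na(values)], values[!is.na(values)],
                            xout = times)$y
  }
  structure(list(times = times, values = values, dt = mean(d),
                 time_unit = time_unit, label = label),
            class = "eco_ts")
}

#' @export
print.eco_ts <- function(x, ...) {
  cat(sprintf("Observable series%s: %d points, dt = %g %s, range [%g, %g]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), x$dt, x$time_unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.eco_ts <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x$times, value = x$values)
}

#' Read an observable series from CSV/TSV
#'
#' Reads a delimited file with a time (or date) column and a value
#' column.  A character time column parseable as dates is converted to a
#' regular numeric index (0, 1, 2, ...) in units of `time_unit`;
#' a numeric time column is used as is.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param time_col,value_col Column names or indices (defaults 1 and 2).
#' @param time_unit,label Passed to [eco_ts()].
#' @return An `"eco_ts"` object.
#' @export
read_time_series <- function(path, time_col = 1, value_col = 2,
                             time_unit = "month", label = basename(path)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  tcol <- df[[time_col]]
  vals <- as.numeric(df[[value_col]])
  if (is.character(tcol)) {
    parsed <- suppressWarnings(as.Date(tcol))
    tcol <- if (!anyNA(parsed)) seq_along(parsed) - 1
            else suppressWarnings(as.numeric(tcol))
    if (anyNA(tcol))
      stop("time column is neither numeric nor parseable as dates",
           call. = FALSE)
  }
  eco_ts(vals, times = as.numeric(tcol), time_unit = time_unit,
         label = label)
}

#' Detrended fluctuation series
#'
#' Residual (stochastic) component of an observable series together with
#' the removed trend estimate and the method used.  Satisfies
#' `trend_estimate + residuals == values` exactly.
#'
#' @keywords internal
fluctuation_series <- function(times, residuals, trend_estimate, method,
                               dt, time_unit, label, detail = list()) {
  structure(list(times = times, residuals = residuals,
                 trend_estimate = trend_estimate, method = method,
                 dt = dt, time_unit = time_unit, label = label,
                 detail = detail),
            class = "fluctuation_series")
}

#' @export
print.fluctuation_series <- function(x, ...) {
  cat(sprintf(
    "Fluctuation series (%s detrend)%s: %d points, sd = %g\n",
    x$method,
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$residuals), stats::sd(x$residuals)))
  if (x$method == "fourier")
    cat(sprintf("  removed %d spike bin(s) (plus DC)\n",
                length(x$detail$spike_bins)))
  invisible(x)
}

#' @export
as.data.frame.fluctuation_series <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(time = x$times,
             value = x$trend_estimate + x$residuals,
             trend = x$trend_estimate,
             residual = x$residuals,
             method = x$method)
}

#' Linear detrending by ordinary least squares
#'
#' Fits a straight line \eqn{a + b t} to the series by OLS and returns
#' the residuals as the fluctuation component.  This is the detrending
#' used for series whose dominant part is a smooth ramp (temperature
#' anomalies, the CO2 growth curve).
#'
#' @param series An [eco_ts()] object.
#' @return A `"fluctuation_series"` (method `"linear"`); `detail` holds
#'   the fitted intercept and slope.
#' @examples
#' ts <- eco_ts(2 + 0.1 * (0:47) + rnorm(48, sd = 0.1))
#' fl <- linear_detrend(ts)
#' @export
linear_detrend <- function(series) {
  stopifnot(inherits(series, "eco_ts"))
  if (length(series$values) < 3) stop("need n >= 3", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, series$times), series$values)
  trend <- series$values - fit$residuals
  fluctuation_series(series$times, fit$residuals, trend, "linear",
                     series$dt, series$time_unit, series$label,
                     detail = list(intercept = unname(fit$coefficients[1]),
                                   slope = unname(fit$coefficients[2])))
}

#' Fourier spike-removal detrending
#'
#' Transforms the series to the frequency domain, removes the DC bin and
#' every bin whose amplitude spikes above the noise floor, and inverts
#' the edited spectrum.  The inverse transform of the removed (spike +
#' DC) spectrum is the trend estimate; the inverse transform of the rest
#' is the fluctuation series.  Conjugate-symmetric bin pairs are always
#' removed together, so both outputs are real; the decomposition is
#' exactly additive and orthogonal (disjoint frequency support).
#'
#' A bin is a spike when its amplitude exceeds `spike_threshold` times
#' the median non-DC amplitude; at most `max_spikes` bin pairs are
#' removed, largest first.  The defaults (4x median, 8 pairs) remove an
#' annual cycle and its strong harmonics from monthly data without
#' touching the noise floor.  For even-length series the self-conjugate
#' Nyquist bin is an ordinary candidate.
#'
#' @param series An [eco_ts()] object with at least 16 points.
#' @param spike_threshold Spike criterion, as a multiple of the median
#'   non-DC amplitude.
#' @param max_spikes Maximum number of spike bin pairs to remove.
#' @return A `"fluctuation_series"` (method `"fourier"`); `detail$spike_bins`
#'   gives the removed bin indices (1-based, DC = 1 excluded implicitly).
#' @examples
#' t <- 0:127
#' ts <- eco_ts(5 + sin(2 * pi * t / 16) + rnorm(128, sd = .05))
#' fl <- fourier_detrend(ts)
#' @export
fourier_detrend <- function(series, spike_threshold = 4, max_spikes = 8) {
  stopifnot(inherits(series, "eco_ts"))
  x <- series$values
  n <- length(x)
  if (n < 16) stop("need n >= 16 for spectral detrending", call. = FALSE)
  if (spike_threshold <= 0) stop("'spike_threshold' must be > 0", call. = FALSE)
  F <- stats::fft(x)
  half <- 2:(floor(n / 2) + 1L)               # unique non-DC bins
  amp <- Mod(F[half])
  # floor the criterion at a small fraction of the peak amplitude so that
  # pure-roundoff bins of a noiseless spectrum are never "spikes"
  med <- max(stats::median(amp), 1e-9 * max(amp))
  cand <- half[amp > spike_threshold * med]
  if (length(cand) == length(half))
    stop("all frequency bins classified as spikes; raise 'spike_threshold'",
         call. = FALSE)
  if (length(cand) > max_spikes)
    cand <- cand[order(Mod(F[cand]), decreasing = TRUE)][seq_len(max_spikes)]
  drop <- unique(c(1L, cand, ifelse(cand > 1L, n + 2L - cand, cand)))
  drop <- drop[drop >= 1L & drop <= n]
  Fres <- F; Fres[drop] <- 0
  resid <- Re(stats::fft(Fres, inverse = TRUE)) / n
  trend <- x - resid
  fluctuation_series(series$times, resid, trend, "fourier",
                     series$dt, series$time_unit, series$label,
                     detail = list(spike_bins = setdiff(sort(cand), 1L),
                                   spike_threshold = spike_threshold,
                                   max_spikes = max_spikes))
}
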
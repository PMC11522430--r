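#' Ensemble of simulated paths
#'
#' Container for Monte Carlo path ensembles: a shared time grid starting
#' at 0, an `n_paths x n_times` matrix of observable values with
#' `paths[, 1]` equal to the common starting value, the ground-truth
#' parameters used, and the RNG seed.
#'
#' @param time Numeric time grid, `time[1] == 0`, strictly increasing.
#' @param paths Numeric matrix, one row per path.
#' @param params_truth List of generating parameters (a
#'   [memory_params()] object, or `list(H = ...)` for fBm).
#' @param seed Integer seed the ensemble was drawn with.
#' @return An object of class `"path_ensemble"`.
#' @keywords internal
path_ensemble <- function(time, paths, params_truth, seed) {
  stopifnot(is.matrix(paths), length(time) == ncol(paths),
            time[1] == 0, all(diff(time) > 0))
  structure(list(time = time, paths = paths,
                 params_truth = params_truth, seed = seed),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf(
    "Path ensemble: %d paths x %d times on [0, %g] (seed %s)\n",
    nrow(x$paths), ncol(x$paths), max(x$time), format(x$seed)))
  invisible(x)
}

#' @describeIn simulate_memory_paths long-format data frame
#'   (`path_id`, `time`, `value`) suitable for CSV export.
#' @param x,row.names,optional,... Usual [as.data.frame()] arguments.
#' @export
as.data.frame.path_ensemble <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    path_id = rep(seq_len(nrow(x$paths)), each = ncol(x$paths)),
    time = rep(x$time, nrow(x$paths)),
    value = as.vector(t(x$paths)))
}

#' Simulate paths of the memory-kernel process
#'
#' Draws Monte Carlo realizations of
#' \deqn{x(T) = x_0 + \int_0^T (T-t)^{(\mu-1)/2}\, t^{(\mu-1)/2}
#'   \sqrt{\sin(\nu t)}\, dB(t).}
#' Each path uses one Brownian driver: a single vector of independent
#' Gaussian increments on a fine uniform grid, shared by every output
#' time \eqn{T_j} of that path (the process at different horizons is a
#' functional of the same noise).  The kernel is evaluated at sub-interval
#' midpoints, which keeps the integrable endpoint singularities
#' (\eqn{(T-t)^{(\mu-1)/2}} at \eqn{t \to T} and \eqn{t^{(\mu-1)/2}} at
#' \eqn{t \to 0}, for \eqn{\mu < 1}) finite while preserving convergence
#' of the variance to the Ito-isometry integral.
#'
#' The output grid is uniform with `n_times` points spanning
#' \eqn{[0, T_{max}]}; internally each output step is refined by `refine`
#' sub-steps for the stochastic integral.
#'
#' @param params A [memory_params()] object.
#' @param x_0 Starting value.
#' @param n_times Number of output grid times (including 0), >= 8.
#' @param n_paths Number of independent paths, >= 1.
#' @param T_max Largest output time; must satisfy `T_max <= pi/nu`.
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @param refine Sub-steps per output step for the integral (default 4).
#' @return A `"path_ensemble"` object.
#' @examples
#' p <- memory_params(0.8, 0.5)
#' ens <- simulate_memory_paths(p, n_times = 32, n_paths = 50, seed = 1)
#' ens
#' @export
simulate_memory_paths <- function(params, x_0 = 0, n_times = 128,
                                  n_paths = 100, T_max = pi / params$nu,
                                  seed, refine = 4) {
  params <- as_memory_params(params)
  if (n_times < 8) stop("'n_times' must be >= 8", call. = FALSE)
  if (n_paths < 1) stop("'n_paths' must be >= 1", call. = FALSE)
  if (refine < 1) stop("'refine' must be >= 1", call. = FALSE)
  if (!is.finite(T_max) || T_max <= 0 || T_max > pi / params$nu * (1 + 1e-12))
    stop(sprintf("'T_max' must lie in (0, pi/nu] = (0, %g]", pi / params$nu),
         call. = FALSE)
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  mu <- params$mu; nu <- params$nu
  tg <- seq(0, T_max, length.out = n_times)
  dt <- (tg[2] - tg[1]) / refine
  M <- (n_times - 1L) * refine
  tm <- (seq_len(M) - 0.5) * dt              # midpoints of the fine grid
  # h(t) = t^((mu-1)/2) sqrt(sin(nu t)) does not depend on the horizon
  h <- tm^((mu - 1) / 2) * sqrt(pmax(sin(nu * tm), 0))
  K <- matrix(0, n_times, M)
  for (j in 2:n_times) {
    idx <- seq_len((j - 1L) * refine)
    K[j, idx] <- (tg[j] - tm[idx])^((mu - 1) / 2) * h[idx] * sqrt(dt)
  }
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n_paths * M), n_paths, M))
  X <- x_0 + Z %*% t(K)
  path_ensemble(tg, X, params, seed)
}

#' Simulate fractional Brownian motion by circulant embedding
#'
#' Exact sampling of fractional Gaussian noise (fGn) with Hurst exponent
#' \eqn{H} by the circulant (Wood--Chan) method: the fGn autocovariance
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} +
#'   |k-1|^{2H}\right)}
#' is embedded in a circulant matrix whose eigenvalues are obtained by
#' the discrete Fourier transform of its first row; complex Gaussian
#' variates weighted by the square-rooted eigenvalues are transformed
#' back, and the first `n` real components are unit-variance fGn.
#' Cumulative summation (with increments scaled by `dt^H`,
#' self-similarity) yields fBm started at 0.
#'
#' \eqn{H = 0.5} reduces to ordinary Brownian motion (independent
#' increments, no memory); \eqn{H < 0.5} gives anti-correlated
#' (subdiffusive) and \eqn{H > 0.5} positively correlated
#' (superdiffusive) increments.
#'
#' @param H Hurst exponent, \eqn{0 < H < 1}.
#' @param n Number of increments per path, >= 2.
#' @param dt Time step.
#' @param n_paths Number of independent paths.
#' @param seed Integer seed.
#' @return A `"path_ensemble"` object with `n + 1` grid times (a 0 is
#'   prepended) and `params_truth = list(H = H)`.
#' @examples
#' bm <- simulate_fbm(0.5, n = 256, n_paths = 10, seed = 1)
#' fbm <- simulate_fbm(0.7, n = 256, n_paths = 10, seed = 1)
#' @export
simulate_fbm <- function(H, n, dt = 1, n_paths = 1, seed) {
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1)
    stop("'H' must satisfy 0 < H < 1", call. = FALSE)
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  acov <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                               abs(k - 1)^(2 * H))
  m <- 2^ceiling(log2(2 * n))
  lam <- NULL
  for (attempt in 0:2) {
    row <- acov(c(0:(m / 2), (m / 2 - 1):1))
    ev <- Re(stats::fft(row))
    if (min(ev) > -1e-8 * max(ev)) { lam <- pmax(ev, 0); break }
    m <- 2 * m                                # enlarge embedding, retry
  }
  if (is.null(lam))
    stop(paste("circulant embedding produced negative eigenvalues;",
               "a larger embedding size is required for this H/n"),
         call. = FALSE)
  half <- m / 2
  fgn <- withr::with_seed(seed, {
    V <- matrix(0i, m, n_paths)
    V[1, ] <- sqrt(lam[1]) * stats::rnorm(n_paths)
    V[half + 1, ] <- sqrt(lam[half + 1]) * stats::rnorm(n_paths)
    k <- 2:half
    Z1 <- matrix(stats::rnorm((half - 1) * n_paths), half - 1, n_paths)
    Z2 <- matrix(stats::rnorm((half - 1) * n_paths), half - 1, n_paths)
    V[k, ] <- sqrt(lam[k] / 2) * (Z1 + 1i * Z2)
    V[m + 2 - k, ] <- Conj(V[k, ])
    Re(stats::mvfft(V))[seq_len(n), , drop = FALSE] / sqrt(m)
  })
  incr <- fgn * dt^H
  X <- rbind(0, apply(incr, 2, cumsum))       # (n+1) x n_paths
  path_ensemble(seq(0, n * dt, by = dt), t(X), list(H = H), seed)
}

#' Build an observable-like series with known trend and noise
#'
#' Generates synthetic series structured like the empirical inputs of
#' the analysis (a dominant deterministic trend plus memory-bearing
#' stochastic fluctuations), with both components recorded as ground
#' truth, so the detrend -> MSD -> fit pipeline can be exercised
#' end-to-end.
#'
#' Trends: `linear` is \eqn{a + b t}; `seasonal_linear` is
#' \eqn{a + b t + c \sin(2\pi t / p + \phi)} (a Keeling-curve-like ramp
#' with a seasonal cycle).
#'
#' Noise: `memory_process` draws one path of the memory-kernel process
#' on its own clock \eqn{[0, \pi/\nu]} sampled at the `n` grid points
#' (so `k` series steps correspond to a process lag of
#' `k * (pi/nu)/(n-1)`); `fbm` draws fractional Brownian motion
#' increments cumulated over the grid.  Both are multiplied by
#' `noise_params$amplitude` (0 gives the pure trend).
#'
#' @param trend `"linear"` or `"seasonal_linear"`.
#' @param trend_params List with `a`, `b` and, for `seasonal_linear`,
#'   `c`, `period`, `phase`.
#' @param noise `"memory_process"` or `"fbm"`.
#' @param noise_params For `memory_process`: `mu`, `nu`, `amplitude`;
#'   for `fbm`: `H`, `amplitude`.
#' @param n Series length, >= 32.
#' @param seed Integer seed.
#' @param dt Time step (default 1).
#' @param time_unit Time unit label.
#' @return An [eco_ts()] with attribute `"truth"`: a list holding the
#'   `trend` and `noise` component vectors and the generating parameters.
#' @examples
#' ts <- make_observable_series(
#'   trend = "seasonal_linear",
#'   trend_params = list(a = 390, b = 0.2, c = 3, period = 12, phase = 0),
#'   noise = "memory_process",
#'   noise_params = list(mu = 0.8, nu = 0.5, amplitude = 1),
#'   n = 144, seed = 7)
#' @export
make_observable_series <- function(trend = c("linear", "seasonal_linear"),
                                   trend_params = list(a = 0, b = 1),
                                   noise = c("memory_process", "fbm"),
                                   noise_params = list(mu = 0.8, nu = 0.5,
                                                       amplitude = 1),
                                   n, seed, dt = 1, time_unit = "month") {
  trend <- match.arg(trend)
  noise <- match.arg(noise)
  if (n < 32) stop("'n' must be >= 32", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  t <- (seq_len(n) - 1) * dt
  tp <- trend_params
  tr <- switch(trend,
    linear = {
      if (!all(c("a", "b") %in% names(tp)))
        stop("linear trend needs trend_params$a and $b", call. = FALSE)
      tp$a + tp$b * t
    },
    seasonal_linear = {
      need <- c("a", "b", "c", "period", "phase")
      if (!all(need %in% names(tp)))
        stop("seasonal_linear trend needs trend_params ",
             paste(need, collapse = ", "), call. = FALSE)
      tp$a + tp$b * t + tp$c * sin(2 * pi * t / tp$period + tp$phase)
    })
  np <- noise_params
  amp <- if (!is.null(np$amplitude)) np$amplitude else 1
  if (!is.numeric(amp) || amp < 0)
    stop("noise_params$amplitude must be >= 0", call. = FALSE)
  nz <- if (amp == 0) {
    numeric(n)
  } else if (noise == "memory_process") {
    if (!all(c("mu", "nu") %in% names(np)))
      stop("memory_process noise needs noise_params$mu and $nu",
           call. = FALSE)
    p <- memory_params(np$mu, np$nu, time_unit)
    ens <- simulate_memory_paths(p, x_0 = 0, n_times = n, n_paths = 1,
                                 T_max = pi / np$nu, seed = seed)
    amp * drop(ens$paths)
  } else {
    if (!("H" %in% names(np)))
      stop("fbm noise needs noise_params$H", call. = FALSE)
    ens <- simulate_fbm(np$H, n = n - 1L, dt = dt, n_paths = 1, seed = seed)
    amp * drop(ens$paths)
  }
  out <- eco_ts(tr + nz, times = t, time_unit = time_unit,
                label = sprintf("synthetic:%s+%s", trend, noise))
  attr(out, "truth") <- list(trend = tr, noise = nz,
                             trend_model = trend, trend_params = tp,
                             noise_model = noise, noise_params = np,
                             seed = seed)
  out
}
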
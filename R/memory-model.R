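#' Memory-process parameters
#'
#' Bundles the two parameters of the memory-bearing stochastic process
#' \deqn{x(T) = x_0 + \int_0^T (T-t)^{(\mu-1)/2}\, t^{(\mu-1)/2}
#'   \sqrt{\sin(\nu t)}\, dB(t),}
#' namely the dimensionless memory parameter \eqn{\mu} and the
#' characteristic frequency \eqn{\nu} (inverse time units).  The process
#' is defined on the time interval \eqn{[0, \pi/\nu]}, where the
#' sinusoidal envelope under the square root stays non-negative.
#'
#' Values \eqn{0 < \mu < 1} put the process in the superdiffusive regime
#' (MSD growing faster than linearly at short times); \eqn{\mu > 1} is
#' admitted by the mathematics and accepted here, since fits may wander
#' above 1.
#'
#' @param mu Memory parameter, must be > 0 (the kernel must be integrable
#'   and \eqn{\Gamma(\mu)} finite).
#' @param nu Characteristic frequency, must be > 0. Carried per
#'   `time_unit`.
#' @param time_unit Unit of the time axis `nu` refers to
#'   (`"month"`, `"week"`, or any label).
#' @return An object of class `"memory_params"`.
#' @examples
#' memory_params(0.94, 0.67)                 # global NEE fit
#' memory_params(0.68, 0.30)                 # global SST fit
#' @export
memory_params <- function(mu, nu, time_unit = "month") {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("'nu' must be a single finite number > 0", call. = FALSE)
  structure(
    list(mu = as.numeric(mu), nu = as.numeric(nu),
         time_unit = as.character(time_unit)),
    class = "memory_params")
}

#' @export
print.memory_params <- function(x, ...) {
  b <- beta_exponent(x)
  cat(sprintf(
    "Memory-process parameters\n  mu = %g (memory parameter)\n  nu = %g per %s (characteristic frequency)\n  domain: 0 <= T <= pi/nu = %g %ss\n  beta = 2*mu = %g  [%s]\n",
    x$mu, x$nu, x$time_unit, pi / x$nu, x$time_unit, b$beta, b$regime))
  invisible(x)
}

as_memory_params <- function(params) {
  if (inherits(params, "memory_params")) return(params)
  if (is.list(params) && all(c("mu", "nu") %in% names(params)))
    return(memory_params(params$mu, params$nu,
                         if (!is.null(params$time_unit)) params$time_unit else "month"))
  stop("'params' must be a memory_params object (see memory_params())",
       call. = FALSE)
}

check_domain <- function(params, T, allow_zero = TRUE) {
  Tmax <- pi / params$nu
  lo <- if (allow_zero) 0 else .Machine$double.xmin
  bad <- !is.finite(T) | T < lo | T > Tmax * (1 + 1e-12)
  if (any(bad))
    stop(sprintf(
      "time T = %g outside the process domain [%s, pi/nu] = [%s, %g]",
      T[which(bad)[1L]], if (allow_zero) "0" else "0 (exclusive)",
      if (allow_zero) "0" else "0", Tmax), call. = FALSE)
  invisible(TRUE)
}

#' Scaling of the theoretical MSD onto an empirical curve
#'
#' The theoretical MSD is matched to empirical curves "without altering
#' its shape" through a time rescaling \eqn{t \mapsto t/t_c} and an
#' amplitude normalization \eqn{N}.  Note that the scaled curve
#' \eqn{N\,\mathrm{MSD}(\mu, \nu, t/t_c)} depends on \eqn{(\nu, t_c, N)}
#' only through \eqn{\omega = \nu/t_c} and one overall amplitude (see
#' [fit_msd()]), so \eqn{t_c} acts as a reporting convention.
#'
#' @param t_c Time rescaling factor, > 0, in the time units of the series.
#' @param N MSD amplitude normalization, > 0, in squared observable units.
#' @return An object of class `"fit_scaling"`.
#' @examples
#' fit_scaling(t_c = 1.273, N = 2.629)
#' @export
fit_scaling <- function(t_c, N) {
  if (!is.numeric(t_c) || length(t_c) != 1L || !is.finite(t_c) || t_c <= 0)
    stop("'t_c' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("'N' must be a single finite number > 0", call. = FALSE)
  structure(list(t_c = as.numeric(t_c), N = as.numeric(N)),
            class = "fit_scaling")
}

#' @export
print.fit_scaling <- function(x, ...) {
  cat(sprintf("MSD scaling: t_c = %g (time), N = %g (amplitude)\n",
              x$t_c, x$N))
  invisible(x)
}

#' Closed-form mean-square displacement of the memory process
#'
#' Evaluates
#' \deqn{\mathrm{MSD}(T) = \sqrt{\pi}\,\Gamma(\mu)\, T^{\mu-1/2}
#'   \nu^{1/2-\mu} \sin(\nu T/2)\, J_{\mu-1/2}(\nu T/2),}
#' the variance of the process displacement after time \eqn{T}, where
#' \eqn{J} is the Bessel function of the first kind.  Defined for
#' \eqn{0 \le T \le \pi/\nu}; by continuity the value at \eqn{T = 0} is 0.
#'
#' For \eqn{\nu T < 10^{-6}} the short-time power law [msd_short_time()]
#' (to which the closed form is asymptotic) is returned instead, avoiding
#' cancellation in the product of vanishing factors.
#'
#' @param params A [memory_params()] object.
#' @param T Time(s), vectorized, each within \eqn{[0, \pi/\nu]}.
#' @return Numeric vector of variances (squared observable units).
#' @seealso [msd_quadrature()] for the independent quadrature route,
#'   [msd_short_time()] for the power-law asymptote, [scaled_msd()].
#' @examples
#' p <- memory_params(0.94, 0.67)
#' msd_closed_form(p, c(0, 1, 2, 4))
#' @export
msd_closed_form <- function(params, T) {
  params <- as_memory_params(params)
  check_domain(params, T)
  mu <- params$mu; nu <- params$nu
  out <- numeric(length(T))
  z <- nu * T
  small <- z < 1e-6                  # includes T = 0 exactly
  if (any(small)) out[small] <- msd_short_time(params, T[small])
  if (any(!small)) {
    Tt <- T[!small]
    out[!small] <- sqrt(pi) * gamma(mu) * Tt^(mu - 0.5) * nu^(0.5 - mu) *
      sin(nu * Tt / 2) * besselJ(nu * Tt / 2, mu - 0.5)
  }
  out
}

#' MSD by direct quadrature of the kernel (independent oracle)
#'
#' By the Ito isometry, the variance of the stochastic integral defining
#' the process equals
#' \deqn{\int_0^T (T-t)^{\mu-1}\, t^{\mu-1} \sin(\nu t)\, dt,}
#' the time integral of the squared kernel.  This routine evaluates that
#' integral numerically and serves as an independent cross-check of
#' [msd_closed_form()].  For \eqn{\mu < 1} both endpoints carry integrable
#' singularities; the integral is split at \eqn{T/2} and each half is
#' regularized by the substitution \eqn{u = t^{\mu}} (resp.
#' \eqn{u = (T-t)^{\mu}}), after which the integrand is bounded.
#'
#' @inheritParams msd_closed_form
#' @param T Time(s), each within \eqn{(0, \pi/\nu]}.
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @return Numeric vector of variances.
#' @examples
#' p <- memory_params(0.68, 0.30)
#' msd_quadrature(p, 2)
#' msd_closed_form(p, 2)
#' @export
msd_quadrature <- function(params, T, rel.tol = 1e-11) {
  params <- as_memory_params(params)
  check_domain(params, T, allow_zero = FALSE)
  mu <- params$mu; nu <- params$nu
  one <- function(Ti) {
    # u = t^mu on [0, T/2]; u = (T-t)^mu on [T/2, T]; both map to
    # [0, (T/2)^mu] with the singular factor absorbed into du.
    g1 <- function(u) { t <- u^(1 / mu); (Ti - t)^(mu - 1) * sin(nu * t) / mu }
    g2 <- function(u) { t <- Ti - u^(1 / mu); t^(mu - 1) * sin(nu * t) / mu }
    up <- (Ti / 2)^mu
    r <- tryCatch({
      i1 <- stats::integrate(g1, 0, up, rel.tol = rel.tol, abs.tol = 0)
      i2 <- stats::integrate(g2, 0, up, rel.tol = rel.tol, abs.tol = 0)
      i1$value + i2$value
    }, error = function(e)
      stop(sprintf("quadrature failed at T = %g (mu = %g, nu = %g): %s",
                   Ti, mu, nu, conditionMessage(e)), call. = FALSE))
    r
  }
  vapply(T, one, numeric(1))
}

#' Short-time power-law asymptote of the MSD
#'
#' For \eqn{T \ll 1} the MSD reduces to the power law
#' \deqn{\mathrm{MSD} \approx b\,T^{\beta}, \qquad \beta = 2\mu, \qquad
#'   b = \frac{\sqrt{\pi}\,\nu\,\Gamma(\mu)}{4^{\mu}\,\Gamma(\mu + 1/2)},}
#' obtained from the small-argument expansions of \eqn{\sin} and of the
#' Bessel factor.  The growth exponent \eqn{\beta = 2\mu} is what
#' classifies the process as sub-/super-diffusive.
#'
#' @inheritParams msd_closed_form
#' @param T Time(s), each \eqn{\ge 0} (the asymptote itself is a global
#'   power law; it approximates the MSD only for small \eqn{T}).
#' @return Numeric vector \eqn{b\,T^{2\mu}}.
#' @examples
#' p <- memory_params(0.5, 1)     # b = pi/2, beta = 1: ordinary diffusion
#' msd_short_time(p, 1:3)
#' @export
msd_short_time <- function(params, T) {
  params <- as_memory_params(params)
  if (any(!is.finite(T) | T < 0))
    stop("'T' must be finite and >= 0", call. = FALSE)
  mu <- params$mu; nu <- params$nu
  b <- sqrt(pi) * nu * gamma(mu) / (4^mu * gamma(mu + 0.5))
  b * T^(2 * mu)
}

#' Superdiffusion exponent and diffusion regime
#'
#' Returns \eqn{\beta = 2\mu}, the short-time MSD growth exponent, with a
#' regime label: subdiffusive (\eqn{\beta < 1}), diffusive
#' (\eqn{\beta = 1}), superdiffusive (\eqn{1 < \beta < 2}), or
#' `"beta >= 2"` for fits above the ballistic threshold.
#'
#' @inheritParams msd_closed_form
#' @return A list with elements `beta` and `regime`.
#' @examples
#' beta_exponent(memory_params(0.94, 0.67))   # beta = 1.88, superdiffusive
#' beta_exponent(memory_params(0.5, 1))       # beta = 1, diffusive
#' @export
beta_exponent <- function(params) {
  params <- as_memory_params(params)
  beta <- 2 * params$mu
  regime <-
    if (beta < 1 - 1e-12) "subdiffusive"
    else if (abs(beta - 1) <= 1e-12) "diffusive"
    else if (beta < 2 - 1e-12) "superdiffusive"
    else "beta >= 2"
  list(beta = beta, regime = regime)
}

#' Endpoint displacement density of the memory process
#'
#' The endpoint \eqn{x(T)} of the process started at \eqn{x_0} is
#' Gaussian with mean \eqn{x_0} and variance
#' \eqn{\sigma^2 = \mathrm{MSD}(T)} from [msd_closed_form()].
#'
#' `form = "normalized"` (the default) uses the proper Gaussian prefactor
#' \eqn{(2\pi\sigma^2)^{-1/2}}, so the density integrates to 1.
#' `form = "as_printed"` reproduces the prefactor
#' \eqn{(2\sigma^2)^{-1/2}} that the source model states literally; that
#' variant integrates to \eqn{\sqrt{\pi}}, not 1 (the exponent fixes the
#' variance either way), and is kept only for comparison.
#'
#' @param x_T Endpoint value(s) at which to evaluate the density.
#' @param x_0 Starting value (default 0).
#' @inheritParams msd_closed_form
#' @param T A single horizon in \eqn{(0, \pi/\nu]}.
#' @param form `"normalized"` or `"as_printed"`.
#' @return Density values at `x_T`.
#' @examples
#' p <- memory_params(0.78, 0.66)
#' memory_pdf(seq(-3, 3, by = 1.5), 0, p, T = 3)
#' @export
memory_pdf <- function(x_T, x_0 = 0, params, T,
                       form = c("normalized", "as_printed")) {
  form <- match.arg(form)
  params <- as_memory_params(params)
  if (length(T) != 1L) stop("'T' must be a single time", call. = FALSE)
  check_domain(params, T, allow_zero = FALSE)
  s2 <- msd_closed_form(params, T)
  if (s2 <= 0)
    stop(sprintf("degenerate distribution: MSD(T = %g) = 0", T),
         call. = FALSE)
  d <- stats::dnorm(x_T, mean = x_0, sd = sqrt(s2))
  if (form == "as_printed") d <- d * sqrt(pi)
  d
}

#' Theoretical MSD rescaled onto an empirical time axis
#'
#' Evaluates \eqn{N \cdot \mathrm{MSD}(\mu, \nu, t/t_c)}: the model curve
#' matched to empirical MSDs by a time rescaling \eqn{t_c} and amplitude
#' normalization \eqn{N}.  Admissible lags satisfy
#' \eqn{t \le t_c\,\pi/\nu}.
#'
#' @inheritParams msd_closed_form
#' @param scaling A [fit_scaling()] object.
#' @param t Lag(s) on the empirical time axis.
#' @return Numeric vector of scaled model MSD values.
#' @examples
#' p <- memory_params(0.94, 0.67)
#' s <- fit_scaling(t_c = 1.273, N = 2.629)
#' scaled_msd(p, s, t = 1:5)
#' @export
scaled_msd <- function(params, scaling, t) {
  params <- as_memory_params(params)
  if (!inherits(scaling, "fit_scaling"))
    stop("'scaling' must be a fit_scaling object", call. = FALSE)
  Tmax <- scaling$t_c * pi / params$nu
  if (any(!is.finite(t) | t < 0 | t > Tmax * (1 + 1e-12)))
    stop(sprintf(
      "lag outside the rescaled domain: admissible lags are 0 <= t <= t_c*pi/nu = %g",
      Tmax), call. = FALSE)
  scaling$N * msd_closed_form(params, t / scaling$t_c)
}

#' Serialize memory parameters (and optional scaling) to JSON
#'
#' @inheritParams msd_closed_form
#' @param scaling Optional [fit_scaling()] object.
#' @return A JSON string, e.g. `{"mu":0.94,"nu":0.67,"time_unit":"month"}`.
#' @export
params_to_json <- function(params, scaling = NULL) {
  params <- as_memory_params(params)
  x <- list(mu = params$mu, nu = params$nu, time_unit = params$time_unit)
  if (!is.null(scaling)) { x$t_c <- scaling$t_c; x$N <- scaling$N }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}
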
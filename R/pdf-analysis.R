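#' Displacement-probability curves at fixed horizons
#'
#' Evaluates the endpoint displacement density of the memory process at
#' each requested horizon \eqn{T} on a common displacement grid — the
#' probability displacement distribution (PDD).  Because the MSD grows
#' with \eqn{T} on the process domain, the peak density decreases as the
#' horizon lengthens.
#'
#' Horizons are interpreted on the model's own (rescaled) time axis,
#' i.e. they are fed directly to the closed-form MSD; when a `scaling`
#' is supplied its amplitude \eqn{N} multiplies the variance (horizons
#' in raw series time can be converted by dividing by `scaling$t_c`
#' first).
#'
#' @param params A [memory_params()] object.
#' @param horizons Horizons \eqn{T}, each in \eqn{(0, \pi/\nu]}
#'   (default the canonical `c(2, 3, 4)`).
#' @param grid Displacement grid; default 1001 points spanning +/- 6
#'   standard deviations at the largest horizon (bounding the trapezoid
#'   normalization error).
#' @param scaling Optional [fit_scaling()]; its `N` scales the variance
#'   into observable units.
#' @param form Passed to [memory_pdf()].
#' @return A list of `"pdd_curve"` objects (fields `displacements`,
#'   `density`, `T`, `params`), one per horizon.
#' @examples
#' curves <- pdd_at_horizons(memory_params(0.94, 0.67))
#' sapply(curves, function(cv) max(cv$density))   # decreasing in T
#' @export
pdd_at_horizons <- function(params, horizons = c(2, 3, 4), grid = NULL,
                            scaling = NULL, form = "normalized") {
  params <- as_memory_params(params)
  Tmax <- pi / params$nu
  bad <- horizons <= 0 | horizons > Tmax * (1 + 1e-12)
  if (any(bad))
    stop(sprintf(
      "horizon T = %g outside the admissible range (0, pi/nu] = (0, %g]",
      horizons[which(bad)[1]], Tmax), call. = FALSE)
  Nsc <- if (is.null(scaling)) 1 else scaling$N
  if (is.null(grid)) {
    s_max <- sqrt(Nsc * max(msd_closed_form(params, horizons)))
    grid <- seq(-6 * s_max, 6 * s_max, length.out = 1001)
  }
  lapply(horizons, function(Ti) {
    s2 <- Nsc * msd_closed_form(params, Ti)
    d <- stats::dnorm(grid, 0, sqrt(s2))
    if (form == "as_printed") d <- d * sqrt(pi)
    structure(list(displacements = grid, density = d, T = Ti,
                   params = params, scaling = scaling, form = form),
              class = "pdd_curve")
  })
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf(
    "Displacement density at T = %g (mu = %g, nu = %g): peak %g at 0\n",
    x$T, x$params$mu, x$params$nu, max(x$density)))
  invisible(x)
}

#' @export
as.data.frame.pdd_curve <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(displacement = x$displacements, density = x$density, T = x$T)
}

#' @export
plot.pdd_curve <- function(x, ...) {
  graphics::plot(x$displacements, x$density, type = "l",
                 xlab = "displacement", ylab = "density",
                 main = sprintf("T = %g", x$T), ...)
  invisible(x)
}

#' Density of a fixed displacement as a function of time
#'
#' Evaluates the endpoint density at a fixed displacement
#' \eqn{\Delta x} across horizons \eqn{T}: the curve rises from ~0 (the
#' narrow early Gaussian carries no mass at \eqn{\Delta x}), peaks where
#' variance growth balances the Gaussian tail — at the interior optimum
#' \eqn{\mathrm{MSD}(T^*) = \Delta x^2} — and then decays.  For
#' \eqn{\Delta x = 0} it is simply \eqn{(2\pi\,\mathrm{MSD}(T))^{-1/2}},
#' monotone decreasing.
#'
#' @param params A [memory_params()] object.
#' @param delta_x The fixed displacement (observable units).
#' @param times Horizon grid, all within \eqn{(0, \pi/\nu]}; default 400
#'   points spanning the domain.
#' @param msd `"exact"` uses the closed-form MSD; `"short_time"` uses
#'   the power-law asymptote \eqn{b T^{2\mu}} instead.
#' @param scaling Optional [fit_scaling()]; `N` scales the variance.
#' @return A data frame with columns `T` and `density`.
#' @examples
#' crv <- pdf_vs_time(memory_params(0.94, 0.67), delta_x = 1.5)
#' crv$T[which.max(crv$density)]
#' @export
pdf_vs_time <- function(params, delta_x, times = NULL,
                        msd = c("exact", "short_time"), scaling = NULL) {
  params <- as_memory_params(params)
  msd <- match.arg(msd)
  if (!is.numeric(delta_x) || length(delta_x) != 1L || !is.finite(delta_x))
    stop("'delta_x' must be a single finite displacement", call. = FALSE)
  Tmax <- pi / params$nu
  if (is.null(times))
    times <- seq(Tmax / 400, Tmax, length.out = 400)
  if (any(times <= 0 | times > Tmax * (1 + 1e-12)))
    stop(sprintf("all times must lie in (0, pi/nu] = (0, %g]", Tmax),
         call. = FALSE)
  Nsc <- if (is.null(scaling)) 1 else scaling$N
  s2 <- Nsc * switch(msd,
                     exact = msd_closed_form(params, times),
                     short_time = msd_short_time(params, times))
  data.frame(T = times, density = stats::dnorm(delta_x, 0, sqrt(s2)))
}
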
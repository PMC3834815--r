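#' Instrument response function specification
#'
#' Parametric description of the instrument response function (IRF) of a
#' TCSPC instrument.  The default emulates an instrument with a response
#' of about 80 ps full-width at half-maximum; the Gaussian shape is the
#' standard idealisation when only the FWHM is known (measured IRFs can
#' be loaded from file with [read_decay_file()] instead).
#'
#' @param fwhm full-width at half-maximum in ps (> 0).
#' @param t0 position of the IRF peak on the time grid, in ns.
#' @param shape currently only `"gaussian"`.
#' @return an object of class `irf_spec`.
#' @export
irf_spec <- function(fwhm = 80, t0 = 2, shape = "gaussian") {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || is.na(fwhm) || fwhm <= 0)
    abort_config("IRF fwhm must be a single positive number (ps)")
  if (!is.numeric(t0) || length(t0) != 1L || is.na(t0))
    abort_config("IRF t0 must be a single number (ns)")
  shape <- match.arg(shape, "gaussian")
  structure(list(fwhm = fwhm, t0 = t0, shape = shape), class = "irf_spec")
}

#' Discretise an IRF onto a time grid
#'
#' Evaluates the parametric IRF on the grid and normalises to unit area
#' (sum of bin values = 1), the convention [reconvolve()] expects.
#'
#' @param spec an [irf_spec()].
#' @param grid time grid from [make_time_grid()] (bin centres, ns).
#' @return a [decay_curve()] holding the unit-area IRF.
#' @export
#' @examples
#' irf <- make_irf(irf_spec(fwhm = 80, t0 = 2), make_time_grid(4096, 50))
#' sum(irf$counts)
make_irf <- function(spec, grid) {
  if (!inherits(spec, "irf_spec")) abort_config("spec must be an irf_spec")
  grid <- as.numeric(grid)
  dt <- grid[2] - grid[1]
  fwhm_ns <- spec$fwhm / 1e3
  if (fwhm_ns < 0.1 * dt)
    abort_config(sprintf(
      "IRF fwhm (%.3g ps) is below 0.1 bin widths (%.3g ps): unresolvable",
      spec$fwhm, dt * 1e3))
  if (spec$t0 < min(grid) || spec$t0 > max(grid))
    abort_config("IRF t0 must lie within the time window")
  window <- max(grid) - min(grid)
  if (fwhm_ns > window)
    warning(sprintf("IRF fwhm (%.3g ns) exceeds the %.3g ns window; the discretized IRF is badly truncated",
                    fwhm_ns, window))
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  y <- exp(-0.5 * ((grid - spec$t0) / sigma)^2)
  s <- sum(y)
  if (s <= 0) abort_config("IRF is zero everywhere on the grid")
  decay_curve(grid, y / s, wavelength = NA_real_,
              metadata = list(kind = "irf", fwhm_ps = spec$fwhm,
                              t0_ns = spec$t0, shape = spec$shape))
}
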
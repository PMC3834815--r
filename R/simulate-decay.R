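#' Noiseless expectation of a multi-exponential TCSPC decay
#'
#' `sum_i A_i exp(-t/tau_i)` convolved with the unit-area IRF.  With
#' `peak_counts = NULL` the raw A-weighted convolution is returned
#' (useful for linearity checks); otherwise it is scaled so its maximum
#' equals `peak_counts`, and `background` is added.
#'
#' @param components a [decay_components()]; if it carries several
#'   A-factor lists the first is used (see [simulate_global_set()]).
#' @param irf IRF as a [decay_curve()] (renormalised internally).
#' @param peak_counts target maximum of the expectation, or `NULL` to
#'   leave the curve unscaled.
#' @param background constant expected background, counts/bin.
#' @param afactors optional explicit A-factor vector overriding the one
#'   stored in `components`.
#' @return numeric vector of expected counts per bin.
#' @export
decay_expectation <- function(components, irf, peak_counts = NULL,
                              background = 0, afactors = NULL) {
  if (!inherits(components, "decay_components"))
    abort_config("components must be a decay_components")
  a <- if (is.null(afactors)) components$afactors[[1]] else as.numeric(afactors)
  dt <- bin_width(irf)
  if (any(components$lifetimes < 1e-3 * dt))
    abort_config("a lifetime is shorter than 1e-3 bin widths: unresolvable")
  model <- decay_model(components$lifetimes,
                       matrix(pmax(a, 0), ncol = 1))
  mu <- reconvolve(model, irf)
  if (!is.null(peak_counts)) {
    m <- max(mu)
    if (m <= 0) abort_config("expectation is identically zero")
    mu <- mu * (peak_counts / m)
  }
  mu + background
}

#' Simulate one TCSPC decay histogram
#'
#' Draws independent Poisson counts around the reconvolved expectation
#' of `components`, scaled to `peak_counts` at its maximum, plus a
#' constant background.  Identical `seed` gives identical output.
#'
#' @inheritParams decay_expectation
#' @param peak_counts expected counts in the peak channel (>= 100).
#' @param background expected background counts per bin (default 0; real
#'   instruments have dark counts, the fitter always estimates one).
#' @param seed integer seed for the Poisson stream.
#' @param wavelength emission wavelength recorded in the output curve.
#' @return a [decay_curve()] of integer counts.
#' @export
#' @examples
#' g <- make_time_grid(512, 25)
#' irf <- make_irf(irf_spec(80, 2), g)
#' d <- simulate_decay(get_preset("duplex"), irf, peak_counts = 1e4, seed = 1)
simulate_decay <- function(components, irf, peak_counts, background = 0,
                           seed = 1L, wavelength = NA_real_,
                           afactors = NULL) {
  if (!is.numeric(peak_counts) || peak_counts < 100)
    abort_config("peak_counts must be at least 100")
  mu <- decay_expectation(components, irf, peak_counts, background, afactors)
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  decay_curve(irf$times, counts, wavelength = wavelength,
              metadata = list(seed = seed, peak_counts = peak_counts,
                              background = background))
}

#' Simulate a linked multi-wavelength decay set
#'
#' One decay per emission wavelength, all sharing the lifetimes of
#' `components`; amplitudes are shared when `components` carries a single
#' A-factor list, or per-wavelength when it carries one list per
#' wavelength.  Each curve draws from an independent substream derived
#' from the master seed and its wavelength, so the set is reproducible
#' and curves are mutually independent.
#'
#' @inheritParams simulate_decay
#' @param wavelengths emission wavelengths in nm (e.g. `c(370, 380, 390)`).
#' @return list of [decay_curve()]s, one per wavelength.
#' @export
simulate_global_set <- function(components, irf, wavelengths,
                                peak_counts = 1e4, background = 0,
                                seed = 1L) {
  if (length(wavelengths) < 1L)
    abort_config("wavelengths must be a non-empty numeric vector")
  na <- length(components$afactors)
  if (na != 1L && na != length(wavelengths))
    abort_config("need one shared A-factor list or one per wavelength")
  lapply(seq_along(wavelengths), function(j) {
    a <- components$afactors[[if (na == 1L) 1L else j]]
    simulate_decay(components, irf, peak_counts, background,
                   seed = substream_seed(seed, wavelengths[j]),
                   wavelength = wavelengths[j], afactors = a)
  })
}
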
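# CD processing chain: average scans -> subtract blank -> smooth ->
# convert to molar units -> exciton metrics.  Every step is linear, so
# order of averaging and subtraction commutes; the chain mirrors the
# standard JASCO acquisition workflow.

#' Average repeated CD scans
#'
#' Pointwise mean of spectra on an identical grid with identical units;
#' `n_scans` accumulates.
#'
#' @param spectra list of [cd_spectrum()] objects.
#' @return a [cd_spectrum()].
#' @export
average_scans <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 1L)
    abort_config("spectra must be a non-empty list of cd_spectrum objects")
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    check_same_cd_grid(ref, s)
    if (s$units != ref$units)
      abort_config("cannot average spectra with different units")
  }
  vals <- rowMeans(vapply(spectra, function(s) s$values,
                          numeric(length(ref$values))))
  cd_spectrum(ref$wavelengths, vals, units = ref$units,
              n_scans = sum(vapply(spectra, function(s) s$n_scans, 1L)),
              metadata = ref$metadata, spacing = NULL)
}

#' Subtract a blank (no-DNA) spectrum
#'
#' Pointwise difference against a baseline spectrum recorded on a sample
#' with the same components but lacking DNA.
#'
#' @param sample,blank [cd_spectrum()] objects on the same grid, same units.
#' @return a [cd_spectrum()].
#' @export
baseline_subtract <- function(sample, blank) {
  check_same_cd_grid(sample, blank)
  if (sample$units != blank$units)
    abort_config("sample and blank must share units before subtraction")
  cd_spectrum(sample$wavelengths, sample$values - blank$values,
              units = sample$units, n_scans = sample$n_scans,
              metadata = sample$metadata, spacing = NULL)
}

#' Means-Movement smoothing (centred moving average)
#'
#' The JASCO "Means-Movement" filter: a centred moving average over
#' `width` points.  At the edges the window shrinks symmetrically, so
#' with `width = 5` the first and last points are unchanged (window 1)
#' and their neighbours use window 3; the grid length never changes.
#'
#' @param spectrum a [cd_spectrum()].
#' @param width odd integer >= 3, in points (not nm).
#' @return a smoothed [cd_spectrum()].
#' @export
smooth_means_movement <- function(spectrum, width = 5L) {
  if (!is.numeric(width) || length(width) != 1L || width < 3 ||
      width != round(width) || width %% 2 == 0)
    abort_config("smoothing width must be an odd integer >= 3")
  y <- spectrum$values
  n <- length(y)
  h <- (width - 1) / 2
  cs <- cumsum(c(0, y))
  idx <- seq_len(n)
  hw <- pmin(h, idx - 1, n - idx)       # shrinking symmetric half-window
  out <- (cs[idx + hw + 1] - cs[idx - hw]) / (2 * hw + 1)
  cd_spectrum(spectrum$wavelengths, out, units = spectrum$units,
              n_scans = spectrum$n_scans, metadata = spectrum$metadata,
              spacing = NULL)
}

# theta[mdeg] = 32980 * delta_epsilon * c[M] * l[cm]; the 32980 factor is
# the standard ellipticity <-> molar-CD conversion.
CD_MDEG_PER_DE <- 32980

#' Convert ellipticity to molar CD per mol 2AP residue
#'
#' `delta_epsilon = theta_mdeg / (32980 * conc_2AP * pathlength)` applied
#' pointwise.  `conc_2AP` is the 2AP *residue* concentration: strand
#' concentration times the number of 2AP residues per strand.
#'
#' @param spectrum a [cd_spectrum()] in mdeg.
#' @param conc_2AP 2AP residue concentration, mol/L (> 0).
#' @param pathlength cuvette pathlength, cm (> 0).
#' @return a [cd_spectrum()] in delta-epsilon units.
#' @export
#' @examples
#' # 32.980 mdeg at 10 uM 2AP residues in a 1 cm cell -> delta-epsilon 0.1
to_delta_epsilon <- function(spectrum, conc_2AP, pathlength = 1) {
  if (spectrum$units != "mdeg")
    abort_config("to_delta_epsilon expects a spectrum in mdeg")
  if (!is.numeric(conc_2AP) || conc_2AP <= 0)
    abort_config("conc_2AP must be positive (mol/L of 2AP residues)")
  if (!is.numeric(pathlength) || pathlength <= 0)
    abort_config("pathlength must be positive (cm)")
  cd_spectrum(spectrum$wavelengths,
              spectrum$values / (CD_MDEG_PER_DE * conc_2AP * pathlength),
              units = "delta_epsilon", n_scans = spectrum$n_scans,
              metadata = spectrum$metadata, spacing = NULL)
}

#' @rdname to_delta_epsilon
#' @export
to_millidegrees <- function(spectrum, conc_2AP, pathlength = 1) {
  if (spectrum$units != "delta_epsilon")
    abort_config("to_millidegrees expects a spectrum in delta_epsilon units")
  if (!is.numeric(conc_2AP) || conc_2AP <= 0)
    abort_config("conc_2AP must be positive (mol/L of 2AP residues)")
  if (!is.numeric(pathlength) || pathlength <= 0)
    abort_config("pathlength must be positive (cm)")
  cd_spectrum(spectrum$wavelengths,
              spectrum$values * (CD_MDEG_PER_DE * conc_2AP * pathlength),
              units = "mdeg", n_scans = spectrum$n_scans,
              metadata = spectrum$metadata, spacing = NULL)
}

#' Exciton-coupling amplitude metrics
#'
#' Summaries of the red-shifted exciton band of a processed (delta-
#' epsilon, smoothed) spectrum: the signal at 330 nm (linear
#' interpolation if 330 nm is off-grid), the band mean over 320-330 nm,
#' and the wavelength of the absolute-value extremum in the 300-360 nm
#' search band.  A spectrum that is identically zero in the band gets
#' `peak_defined = FALSE`.
#'
#' @param spectrum a [cd_spectrum()] in delta-epsilon units.
#' @return object of class `exciton_metrics`: list with `amplitude_330`,
#'   `band_mean_320_330`, `peak_wavelength`, `peak_defined`.
#' @export
exciton_metrics <- function(spectrum) {
  if (spectrum$units != "delta_epsilon")
    abort_config("exciton_metrics expects delta_epsilon units")
  wl <- spectrum$wavelengths
  if (min(wl) > 320 || max(wl) < 330)
    abort_config("spectrum does not cover the 320-330 nm exciton band")
  v <- spectrum$values
  amp330 <- stats::approx(wl, v, xout = 330, rule = 1)$y
  band <- wl >= 320 & wl <= 330
  band_mean <- mean(v[band])
  search <- which(wl >= 300 & wl <= 360)
  if (length(search) == 0)
    abort_config("spectrum does not cover the 300-360 nm search band")
  peak_defined <- any(v[search] != 0)
  peak_wl <- if (peak_defined) wl[search[which.max(abs(v[search]))]]
             else NA_real_
  structure(list(amplitude_330 = amp330, band_mean_320_330 = band_mean,
                 peak_wavelength = peak_wl, peak_defined = peak_defined),
            class = "exciton_metrics")
}

#' @export
print.exciton_metrics <- function(x, ...) {
  cat(sprintf(
    "<exciton_metrics> d-eps(330) = %.4g, mean(320-330) = %.4g, peak %s nm\n",
    x$amplitude_330, x$band_mean_320_330,
    if (x$peak_defined) sprintf("%.1f", x$peak_wavelength) else "undefined"))
  invisible(x)
}

#' Percentage change in exciton signal between conditions
#'
#' `100 * (1 - sample / reference)` on the 330 nm amplitude: 83 means the
#' sample retains 17% of the reference signal; negative values mean the
#' signal grew.
#'
#' @param sample_metrics,reference_metrics [exciton_metrics()] objects.
#' @param statistic which amplitude to compare: the 330 nm point value
#'   (default, matching the published convention) or the 320-330 nm band
#'   mean as a robustness alternative.
#' @return percentage (may be negative).
#' @export
percent_signal_change <- function(sample_metrics, reference_metrics,
                                  statistic = c("amplitude_330",
                                                "band_mean_320_330")) {
  statistic <- match.arg(statistic)
  r <- reference_metrics[[statistic]]
  s <- sample_metrics[[statistic]]
  if (!is.finite(r) || r == 0)
    stop_stackprobe("stackprobe_reference_error",
                    "reference exciton amplitude is zero: percent change undefined")
  100 * (1 - s / r)
}
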
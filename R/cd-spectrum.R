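#' Circular dichroism spectrum
#'
#' Wavelength-resolved CD signal, either raw ellipticity in millidegrees
#' (`units = "mdeg"`) or molar CD per mol 2AP residue
#' (`units = "delta_epsilon"`, M^-1 cm^-1).  The low-energy window used
#' for 2AP exciton work is 300-480 nm sampled every 0.5 nm.
#'
#' @param wavelengths nm, strictly increasing, uniformly spaced.
#' @param values signal values, same length as `wavelengths`.
#' @param units `"mdeg"` or `"delta_epsilon"`.
#' @param n_scans number of accumulated scans this spectrum averages.
#' @param metadata named list (sample, buffer, ...).
#' @param spacing expected grid spacing in nm; set `NULL` to skip the
#'   spacing check (default enforces the 0.5 nm acquisition convention).
#' @return object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, values, units = c("mdeg", "delta_epsilon"),
                        n_scans = 1L, metadata = list(), spacing = 0.5) {
  units <- match.arg(units)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    abort_format("wavelengths and values must have the same length")
  if (length(wavelengths) < 3L)
    abort_format("a CD spectrum needs at least three points")
  d <- diff(wavelengths)
  if (any(d <= 0)) abort_format("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6) abort_format("wavelength grid must be uniform")
  if (!is.null(spacing) && abs(d[1] - spacing) > 1e-6)
    abort_format(sprintf(
      "wavelength spacing is %.4g nm, expected %.4g nm (pass spacing = NULL to override)",
      d[1], spacing))
  if (any(!is.finite(values))) abort_format("CD values must be finite")
  structure(list(wavelengths = wavelengths, values = values, units = units,
                 n_scans = as.integer(n_scans), metadata = metadata),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %g-%g nm (%d pts, %g nm), units %s, %d scan(s)\n",
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths),
              x$wavelengths[2] - x$wavelengths[1], x$units, x$n_scans))
  invisible(x)
}

check_same_cd_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      max(abs(a$wavelengths - b$wavelengths)) > 1e-6)
    abort_grid("CD spectra are not on the same wavelength grid")
  invisible(TRUE)
}

#' Exciton couplet specification for synthetic CD spectra
#'
#' Phenomenological two-Gaussian-lobe model of the bisignate CD signal
#' of an exciton-coupled 2AP dimer.  Only the red-shifted lobe falls on
#' the observable 300-480 nm grid (the blue lobe is buried under DNA
#' absorption below 300 nm); its default centre of 326 nm matches a
#' signal maximal at 320-330 nm.  `unpaired_fraction` is the fraction of
#' molecules whose 2AP pair has lost coupling; the couplet amplitude
#' scales as `1 - unpaired_fraction`.
#'
#' @param lobe_centers centres of the (blue, red) lobes, nm; the red lobe
#'   must lie in 300-480 nm.
#' @param lobe_widths Gaussian sigmas, nm.
#' @param lobe_amplitudes peak delta-epsilon of each lobe, opposite signs
#'   (M^-1 cm^-1 per mol 2AP).
#' @param unpaired_fraction in `[0, 1]`.
#' @param noise_sd Gaussian noise per point, delta-epsilon units.
#' @param baseline_coeffs polynomial baseline coefficients in the reduced
#'   variable `x = (wavelength - 390) / 90` (so the window maps to
#'   `[-1, 1]`), lowest order first.
#' @return object of class `cd_couplet_spec`.
#' @export
cd_couplet_spec <- function(lobe_centers = c(285, 326),
                            lobe_widths = c(12, 12),
                            lobe_amplitudes = c(-4, 4),
                            unpaired_fraction = 0,
                            noise_sd = 0,
                            baseline_coeffs = 0) {
  if (length(lobe_centers) != 2 || length(lobe_widths) != 2 ||
      length(lobe_amplitudes) != 2)
    abort_config("lobe_centers, lobe_widths, lobe_amplitudes must have length 2")
  if (lobe_centers[2] < 300 || lobe_centers[2] > 480)
    abort_config("the red (visible) lobe centre must lie in 300-480 nm")
  if (any(lobe_widths <= 0)) abort_config("lobe widths must be positive")
  if (prod(sign(lobe_amplitudes)) >= 0)
    abort_config("lobe amplitudes must have opposite signs (bisignate couplet)")
  if (unpaired_fraction < 0 || unpaired_fraction > 1)
    abort_config("unpaired_fraction must be in [0, 1]")
  if (noise_sd < 0) abort_config("noise_sd must be non-negative")
  structure(list(lobe_centers = as.numeric(lobe_centers),
                 lobe_widths = as.numeric(lobe_widths),
                 lobe_amplitudes = as.numeric(lobe_amplitudes),
                 unpaired_fraction = unpaired_fraction,
                 noise_sd = noise_sd,
                 baseline_coeffs = as.numeric(baseline_coeffs)),
            class = "cd_couplet_spec")
}

cd_default_grid <- function() seq(300, 480, by = 0.5)

#' Simulate a low-energy exciton CD spectrum
#'
#' `value = (1 - unpaired_fraction) * couplet + baseline + noise`, with
#' the couplet the sum of the two Gaussian lobes of `spec` evaluated on
#' the (>= 300 nm) grid.  `unpaired_fraction = 1` gives exactly zero
#' couplet contribution.  The generator works in delta-epsilon units;
#' use [to_millidegrees()] to emulate raw instrument output.
#'
#' @param spec a [cd_couplet_spec()].
#' @param grid wavelength grid in nm, within 300-480.
#' @param seed integer seed for the noise stream.
#' @param metadata passed to the returned [cd_spectrum()].
#' @return a [cd_spectrum()] in delta-epsilon units.
#' @export
#' @examples
#' s <- simulate_cd_spectrum(cd_couplet_spec(unpaired_fraction = 0.83), seed = 1)
simulate_cd_spectrum <- function(spec, grid = cd_default_grid(), seed = 1L,
                                 metadata = list()) {
  if (!inherits(spec, "cd_couplet_spec"))
    abort_config("spec must be a cd_couplet_spec")
  grid <- as.numeric(grid)
  if (min(grid) < 300 - 1e-9 || max(grid) > 480 + 1e-9)
    abort_config("CD grid must lie within 300-480 nm")
  couplet <- spec$lobe_amplitudes[1] *
    exp(-0.5 * ((grid - spec$lobe_centers[1]) / spec$lobe_widths[1])^2) +
    spec$lobe_amplitudes[2] *
    exp(-0.5 * ((grid - spec$lobe_centers[2]) / spec$lobe_widths[2])^2)
  x <- (grid - 390) / 90
  baseline <- rep(0, length(grid))
  for (k in seq_along(spec$baseline_coeffs))
    baseline <- baseline + spec$baseline_coeffs[k] * x^(k - 1)
  noise <- if (spec$noise_sd > 0)
    with_seed(seed, stats::rnorm(length(grid), 0, spec$noise_sd))
  else rep(0, length(grid))
  vals <- (1 - spec$unpaired_fraction) * couplet + baseline + noise
  cd_spectrum(grid, vals, units = "delta_epsilon", n_scans = 1L,
              metadata = c(metadata,
                           list(seed = seed,
                                unpaired_fraction = spec$unpaired_fraction)),
              spacing = NULL)
}
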
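# Shared small-scale fixtures: a 1024-channel, 25 ns grid (12.2 ps bins,
# enough to resolve the ~50 ps component) keeps unit tests fast; the
# acceptance tests use the full 4096 x 50 ns convention.

small_grid <- function() make_time_grid(1024, 25)

small_irf <- function(fwhm = 80, t0 = 2) make_irf(irf_spec(fwhm, t0), small_grid())

# An IRF that is numerically a delta function: all mass in one bin.
delta_irf <- function(grid = small_grid(), channel = 82L) {
  y <- numeric(length(grid))
  y[channel] <- 1
  decay_curve(grid, y)
}

noiseless_curve <- function(components, irf, peak = 1e4, wavelength = NA) {
  decay_curve(irf$times, decay_expectation(components, irf, peak),
              wavelength = wavelength)
}

# Population-weighted mixture of two preset expectations: each state
# enters with unit total amplitude (per-molecule decay), the physically
# meaningful 50:50, then the sum is scaled to a common peak.
mixture_curve <- function(f, comp_ds, comp_ss, irf, peak = 1e4) {
  mu <- (1 - f) * decay_expectation(comp_ds, irf) +
    f * decay_expectation(comp_ss, irf)
  decay_curve(irf$times, mu * (peak / max(mu)))
}

ref_fit_for <- function(preset_name, irf, peak = 1e4) {
  comp <- get_preset(preset_name)
  fit_global(noiseless_curve(comp, irf, peak), irf,
             length(comp$lifetimes), fit_shift = FALSE)
}
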
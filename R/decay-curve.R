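#' TCSPC decay histogram
#'
#' Container for a single time-correlated single photon counting (TCSPC)
#' histogram: a uniform time grid (bin centres, ns) and per-bin counts.
#' The same container holds measured/simulated decays (integer counts),
#' noiseless model expectations, and instrument response functions
#' (IRFs, typically normalised to unit area and therefore non-integer).
#'
#' @param times numeric vector of bin centres in ns; must be uniformly
#'   spaced and strictly increasing.
#' @param counts numeric vector of non-negative per-bin values, same
#'   length as `times`.
#' @param wavelength emission wavelength in nm, or `NA` (e.g. for an IRF).
#' @param metadata named list of free-form metadata (coerced to character
#'   on file round-trip).
#' @return an object of class `decay_curve`.
#' @export
#' @examples
#' grid <- make_time_grid(64, 6.4)
#' decay_curve(grid, rpois(64, 50), wavelength = 380)
decay_curve <- function(times, counts, wavelength = NA_real_,
                        metadata = list()) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    abort_format("times and counts must have the same length")
  if (length(times) < 2L)
    abort_format("a decay curve needs at least two bins")
  dt <- diff(times)
  if (any(dt <= 0))
    abort_format("time grid must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    abort_format("time grid must be uniform")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort_format("counts must be finite and non-negative")
  structure(
    list(times = times, counts = counts,
         wavelength = as.numeric(wavelength),
         metadata = metadata),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "<decay_curve> %d channels, %.4g-%.4g ns (dt = %.4g ps)%s, %s counts\n",
    length(x$times), min(x$times), max(x$times), bin_width(x) * 1e3,
    if (is.finite(x$wavelength)) sprintf(", %g nm", x$wavelength) else "",
    format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

bin_width <- function(curve) {
  if (inherits(curve, "decay_curve")) curve$times[2] - curve$times[1]
  else curve[2] - curve[1]
}

check_same_grid <- function(a, b, what = "curves") {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9 * bin_width(a))
    abort_grid(sprintf("%s are not on the same time grid", what))
  invisible(TRUE)
}

#' Uniform TCSPC time grid
#'
#' Bin centres of a uniform histogram grid: `n_channels` bins of width
#' `window / n_channels` spanning `[0, window)` ns.
#'
#' @param n_channels number of histogram channels (>= 64).
#' @param window total time window in ns (> 0).
#' @return numeric vector of bin centres (ns).
#' @export
#' @examples
#' g <- make_time_grid(4096, 50)   # ~12.2 ps bins
#' g[2] - g[1]
make_time_grid <- function(n_channels, window) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      is.na(n_channels) || n_channels < 64 ||
      n_channels != round(n_channels))
    abort_config("n_channels must be a single integer >= 64")
  if (!is.numeric(window) || length(window) != 1L ||
      is.na(window) || window <= 0)
    abort_config("window must be a single positive number (ns)")
  dt <- window / n_channels
  (seq_len(n_channels) - 0.5) * dt
}
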
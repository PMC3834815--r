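# Forward model of iterative reconvolution: discrete causal convolution
# of a multi-exponential decay with the measured (unit-area) IRF.
#
# For one component, conv[k] = sum_{j<=k} irf[j] * exp(-(k-j) dt / tau)
# obeys the exact recursion conv[k] = a * conv[k-1] + irf[k] with
# a = exp(-dt/tau); stats::filter evaluates it in C.  This is the
# classic O(N) TCSPC convolution and is bitwise-independent of the
# O(N^2) direct sum used as oracle in the tests.

conv_exp_irf <- function(irf_counts, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(irf_counts, a, method = "recursive"))
}

# Shift a histogram by `s` channels (positive = later), linear
# interpolation for the fractional part; bins shifted in from outside
# the window are zero.
shift_histogram <- function(y, s) {
  if (s == 0) return(y)
  n <- length(y)
  k <- floor(s)
  f <- s - k
  lag_by <- function(y, m) {           # y displaced m channels later
    if (m >= n || m <= -n) return(numeric(n))
    if (m >= 0) c(numeric(m), y[seq_len(n - m)])
    else c(y[(1 - m):n], numeric(-m))
  }
  (1 - f) * lag_by(y, k) + f * lag_by(y, k + 1)
}

#' Multi-exponential decay model with linked lifetimes
#'
#' Parameter set for one or several decay curves fitted jointly: one
#' shared lifetime vector, plus per-curve amplitudes, background and
#' channel shift.  Fractional amplitudes (A factors) are derived as
#' `A[i,j] = alpha[i,j] / sum_i alpha[i,j]`.
#'
#' @param lifetimes shared lifetimes in ns, positive, ascending.
#' @param amplitudes matrix (`n_components` x `n_curves`) of non-negative
#'   pre-exponential amplitudes, in counts at t = 0; a vector is treated
#'   as a single-curve matrix.
#' @param background per-curve constant background, counts/bin.
#' @param shift per-curve IRF shift in channels (real-valued).
#' @return object of class `decay_model`.
#' @export
decay_model <- function(lifetimes, amplitudes, background = NULL,
                        shift = NULL) {
  lifetimes <- as.numeric(lifetimes)
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    abort_config("model lifetimes must be positive")
  if (is.unsorted(lifetimes))
    abort_config("model lifetimes must be ascending")
  if (!is.matrix(amplitudes)) amplitudes <- matrix(amplitudes, ncol = 1)
  if (nrow(amplitudes) != length(lifetimes))
    abort_config("amplitudes must have one row per lifetime")
  if (any(amplitudes < 0))
    abort_config("amplitudes must be non-negative")
  nc <- ncol(amplitudes)
  if (is.null(background)) background <- numeric(nc)
  if (is.null(shift)) shift <- numeric(nc)
  if (length(background) != nc || length(shift) != nc)
    abort_config("background and shift need one entry per curve")
  structure(
    list(n_components = length(lifetimes), lifetimes = lifetimes,
         amplitudes = amplitudes, background = as.numeric(background),
         shift = as.numeric(shift)),
    class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> %d components, %d curve(s)\n",
              x$n_components, ncol(x$amplitudes)))
  A <- model_afactors(x)
  for (i in seq_len(x$n_components))
    cat(sprintf("  tau%d = %.4g ns   A = %s\n", i, x$lifetimes[i],
                paste(sprintf("%.3f", A[i, ]), collapse = " ")))
  invisible(x)
}

# A factors per curve from raw amplitudes (columns sum to 1).
model_afactors <- function(model) {
  A <- model$amplitudes
  csum <- colSums(A)
  csum[csum == 0] <- 1
  sweep(A, 2, csum, "/")
}

#' Reconvolved model expectation for one curve
#'
#' Computes the expected counts per bin for curve `curve_index` of a
#' [decay_model()]: the causal discrete convolution of
#' `sum_i alpha[i] * exp(-t/tau[i])` with the unit-area IRF displaced by
#' the curve's channel shift, plus the curve's constant background.
#'
#' @param model a [decay_model()].
#' @param irf a [decay_curve()] holding the IRF on the data grid; it is
#'   renormalised to unit area internally.
#' @param curve_index which curve's amplitudes/background/shift to use.
#' @param grid optional explicit time grid; defaults to the IRF grid.
#' @return numeric vector of expected counts per bin.
#' @export
#' @examples
#' g <- make_time_grid(256, 25)
#' irf <- make_irf(irf_spec(80, 2), g)
#' m <- decay_model(c(0.5, 5), matrix(c(300, 700), ncol = 1))
#' mu <- reconvolve(m, irf)
reconvolve <- function(model, irf, curve_index = 1L, grid = NULL) {
  if (!inherits(model, "decay_model")) abort_config("model must be a decay_model")
  if (!inherits(irf, "decay_curve")) abort_config("irf must be a decay_curve")
  if (!is.null(grid)) {
    if (length(grid) != length(irf$times) ||
        max(abs(grid - irf$times)) > 1e-9 * bin_width(irf))
      abort_grid("data grid and IRF grid differ")
  }
  j <- as.integer(curve_index)
  if (j < 1L || j > ncol(model$amplitudes))
    abort_config("curve_index out of range")
  dt <- bin_width(irf)
  p <- irf$counts / sum(irf$counts)
  p <- shift_histogram(p, model$shift[j])
  mu <- rep(model$background[j], length(p))
  for (i in seq_len(model$n_components)) {
    a <- model$amplitudes[i, j]
    if (a > 0) mu <- mu + a * conv_exp_irf(p, dt, model$lifetimes[i])
  }
  mu
}
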
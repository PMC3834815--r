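#' Parametric-bootstrap parameter uncertainties
#'
#' Simulates `n_boot` Poisson replicates of the fitted expectations,
#' refits each (warm-started from the converged model), and reports the
#' relative standard deviation of every lifetime and A factor across
#' replicates.  Chosen over the asymptotic covariance matrix because
#' multi-exponential parameters are strongly correlated.
#'
#' @param result a converged `global_fit_result`.
#' @param curves,irf the data and IRF the fit was run on.
#' @param n_boot number of bootstrap replicates (default 50).
#' @param seed master seed; replicate streams are derived from it.
#' @param fit_shift,fit_range passed through to [fit_global()].
#' @return list with `tau_rel_sd` (per lifetime), `afactor_rel_sd`
#'   (per-sample A factors), `afactor_rel_sd_per_curve` (matrix), and the
#'   bootstrap draws themselves.
#' @export
estimate_uncertainties <- function(result, curves, irf, n_boot = 50L,
                                   seed = 1L, fit_shift = TRUE,
                                   fit_range = NULL) {
  if (!inherits(result, "global_fit_result"))
    abort_config("result must be a global_fit_result")
  if (!result$converged)
    abort_state("cannot bootstrap an unconverged fit")
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  n <- result$model$n_components
  nc <- length(curves)
  taus <- matrix(NA_real_, n_boot, n)
  A_samp <- matrix(NA_real_, n_boot, n)
  A_curve <- array(NA_real_, c(n_boot, n, nc))
  for (b in seq_len(n_boot)) {
    rep_curves <- lapply(seq_len(nc), function(j) {
      mu <- pmax(result$expectations[[j]], 0)
      cnt <- with_seed(substream_seed(seed, paste0("boot", b, "_", j)),
                       stats::rpois(length(mu), mu))
      decay_curve(curves[[j]]$times, cnt,
                  wavelength = curves[[j]]$wavelength)
    })
    fit <- fit_global(rep_curves, irf, n, init = result$model,
                      fit_shift = fit_shift, fit_range = fit_range)
    taus[b, ] <- fit$model$lifetimes
    A_samp[b, ] <- a_factors(fit, per_sample = TRUE)
    A_curve[b, , ] <- a_factors(fit)
  }
  rel_sd <- function(x, truth) stats::sd(x) / abs(truth)
  tau_true <- result$model$lifetimes
  A_true_samp <- a_factors(result, per_sample = TRUE)
  A_true_curve <- a_factors(result)
  list(
    tau_rel_sd = vapply(seq_len(n), function(i)
      rel_sd(taus[, i], tau_true[i]), numeric(1)),
    afactor_rel_sd = vapply(seq_len(n), function(i)
      rel_sd(A_samp[, i], A_true_samp[i]), numeric(1)),
    afactor_rel_sd_per_curve = vapply(seq_len(nc), function(j)
      vapply(seq_len(n), function(i)
        rel_sd(A_curve[, i, j], A_true_curve[i, j]), numeric(1)),
      numeric(n)),
    n_boot = n_boot, seed = seed,
    tau_draws = taus, afactor_draws = A_samp)
}
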
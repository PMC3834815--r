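#' Select the number of decay components
#'
#' Fits 1, 2, ... `max_components` exponentials globally and accepts
#' `n + 1` over `n` when (a) the F statistic for the chi-square decrease
#' is significant at `alpha` and (b) every component of the larger model
#' carries an A factor of at least `min_afactor` in at least one curve
#' (a significant but vanishing component is treated as overfitting).
#' Returns the last accepted order.
#'
#' @inheritParams fit_global
#' @param max_components largest order tried (<= 6).
#' @param alpha significance level of the F test.
#' @param min_afactor minimum A factor a component must reach in some
#'   curve for the larger model to be accepted.
#' @param verbose print the chi-square ladder.
#' @return integer: selected number of components.  The per-order fits
#'   are attached as attribute `"fits"`.
#' @export
select_model_order <- function(curves, irf, max_components = 6L,
                               alpha = 0.05, min_afactor = 0.005,
                               fit_shift = TRUE, verbose = FALSE) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  if (max_components < 1 || max_components > 6)
    abort_config("max_components must be in 1..6")
  fits <- vector("list", max_components)
  fits[[1]] <- fit_global(curves, irf, 1L, fit_shift = fit_shift)
  selected <- 1L
  n_bins_total <- sum(vapply(fits[[1]]$fit_range,
                             function(r) r[2] - r[1] + 1L, integer(1)))
  for (n in seq_len(max_components - 1L)) {
    cur <- fits[[selected]]
    nxt <- fit_global(curves, irf, selected + 1L, fit_shift = fit_shift)
    fits[[selected + 1L]] <- nxt
    chisq_cur <- cur$chisq_reduced$global * (n_bins_total - cur$n_free_params)
    chisq_nxt <- nxt$chisq_reduced$global * (n_bins_total - nxt$n_free_params)
    dp <- nxt$n_free_params - cur$n_free_params
    dof_nxt <- n_bins_total - nxt$n_free_params
    f_stat <- ((chisq_cur - chisq_nxt) / dp) / (chisq_nxt / dof_nxt)
    p_f <- stats::pf(f_stat, dp, dof_nxt, lower.tail = FALSE)
    a_max <- apply(a_factors(nxt), 1, max)
    keeps_mass <- all(a_max >= min_afactor)
    if (verbose)
      message(sprintf(
        "order %d -> %d: chi2 %.6g -> %.6g, F = %.3g (p = %.3g), min max-A = %.4g",
        selected, selected + 1L, chisq_cur, chisq_nxt, f_stat, p_f, min(a_max)))
    if (is.finite(p_f) && p_f < alpha && keeps_mass && nxt$converged)
      selected <- selected + 1L
    else
      break
  }
  structure(selected, fits = fits[!vapply(fits, is.null, TRUE)])
}
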
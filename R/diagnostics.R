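#' Reduced chi-square of a fitted decay
#'
#' `sum w_k (C_k - M_k)^2 / dof` with Poisson weights
#' (`w_k = 1/max(C_k, 1)` by default) over the fit range, where
#' `dof = n_bins - n_free_params`.
#'
#' @param curve a [decay_curve()] (or a bare counts vector).
#' @param expectation model expectation, same length.
#' @param n_free_params number of fitted parameters attributed to this
#'   curve (may be fractional when shared parameters are apportioned).
#' @param fit_range `NULL` for all bins, or `c(first, last)` channels.
#' @param weighting `"neyman"` (default) or `"pearson"`.
#' @return the reduced chi-square (non-negative scalar).
#' @export
reduced_chisq <- function(curve, expectation, n_free_params = 0,
                          fit_range = NULL,
                          weighting = c("neyman", "pearson")) {
  counts <- if (inherits(curve, "decay_curve")) curve$counts else as.numeric(curve)
  if (length(counts) != length(expectation))
    abort_config("counts and expectation must have the same length")
  idx <- if (is.null(fit_range)) seq_along(counts)
         else seq.int(fit_range[1], fit_range[2])
  if (!length(idx)) abort_config("fit range is empty")
  dof <- length(idx) - n_free_params
  if (dof <= 0) abort_config("degrees of freedom must be positive")
  w <- poisson_weights(counts[idx], expectation[idx], weighting)
  sum(w * (counts[idx] - expectation[idx])^2) / dof
}

#' Runs test for residual randomness
#'
#' Two-sided Wald-Wolfowitz runs test on the signs of the weighted
#' residuals (normal approximation).  Small p-values flag residuals that
#' are too clustered (systematic misfit) or too regular.
#'
#' @param weighted_residuals numeric vector, length >= 20.  Zeros count
#'   as positive.
#' @return p-value in `[0, 1]`; residuals all of one sign give 0.
#' @export
#' @examples
#' residual_randomness(rep(c(1, -1), 50))  # perfectly alternating: tiny p
residual_randomness <- function(weighted_residuals) {
  r <- as.numeric(weighted_residuals)
  if (length(r) < 20)
    abort_config("runs test needs at least 20 residuals")
  s <- r >= 0
  n_pos <- sum(s)
  n_neg <- sum(!s)
  if (n_pos == 0 || n_neg == 0) return(0)
  n <- n_pos + n_neg
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n_pos * n_neg / n
  sigma2 <- 2 * n_pos * n_neg * (2 * n_pos * n_neg - n) / (n^2 * (n - 1))
  if (sigma2 <= 0) return(0)
  z <- (runs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
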
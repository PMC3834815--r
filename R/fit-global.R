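# Global iterative-reconvolution fitting.
#
# The weighted least-squares problem is separable: for fixed lifetimes
# and shifts, the per-curve amplitudes and background are linear and are
# profiled out by (non-negativity-clamped) weighted linear least squares
# at every objective evaluation (variable projection).  A
# Levenberg-Marquardt damped least-squares loop with forward-difference
# numerical derivatives then drives only the nonlinear parameters:
# log-lifetimes (shared across curves; log-space enforces positivity)
# and optionally one IRF shift per curve.

#' Default Poisson weights for TCSPC least squares
#'
#' Neyman weighting `w = 1/max(C, 1)`, the convention of standard TCSPC
#' software; `pearson` uses `w = 1/max(M, 1)` with the model expectation
#' `M` instead (iteratively reweighted by the fitter).
#' @keywords internal
poisson_weights <- function(counts, expectation = NULL,
                            weighting = c("neyman", "pearson")) {
  weighting <- match.arg(weighting)
  if (weighting == "neyman") 1 / pmax(counts, 1)
  else 1 / pmax(expectation, 1)
}

#' Default channel fit range
#'
#' From 10 channels before the IRF peak to the last channel whose counts
#' exceed the background estimate (median of the pre-rise region), so
#' empty tail channels beyond the decay do not dilute the statistics.
#'
#' @param curve a [decay_curve()].
#' @param irf the IRF [decay_curve()].
#' @param pre_channels channels before the IRF peak to include.
#' @return integer vector `c(first, last)`.
#' @export
default_fit_range <- function(curve, irf, pre_channels = 10L) {
  peak <- which.max(irf$counts)
  first <- max(1L, peak - pre_channels)
  pre <- curve$counts[seq_len(max(peak - 20L, 0L))]
  bg_est <- if (length(pre) >= 5) stats::median(pre) else 0
  above <- which(curve$counts > bg_est)
  last <- if (length(above)) max(above) else length(curve$counts)
  last <- max(last, first + 49L)
  c(first, min(last, length(curve$counts)))
}

# Profiled linear solve for one curve: given the (shifted-IRF-convolved)
# component basis B and weights, solve for amplitudes >= 0 and a free
# background by clamped weighted least squares.
solve_linear_curve <- function(B, y, w, fit_background = TRUE) {
  n <- ncol(B)
  X <- if (fit_background) cbind(B, 1) else B
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  active <- rep(TRUE, n)
  beta <- numeric(ncol(X))
  repeat {
    cols <- which(c(active, rep(TRUE, ncol(X) - n)))
    fit <- stats::.lm.fit(Xw[, cols, drop = FALSE], yw)
    b <- numeric(ncol(X))
    cf <- fit$coefficients
    cf[is.na(cf) | !is.finite(cf)] <- 0
    b[cols] <- cf
    neg <- which(b[seq_len(n)] < 0 & active)
    if (!length(neg)) { beta <- b; break }
    active[neg] <- FALSE
    if (!any(active)) { beta <- b; beta[seq_len(n)] <- 0
      if (ncol(X) > n) {
        bgfit <- stats::.lm.fit(Xw[, ncol(X), drop = FALSE], yw)
        beta[ncol(X)] <- bgfit$coefficients
      }
      break }
  }
  list(alpha = beta[seq_len(n)],
       background = if (fit_background) beta[n + 1] else 0)
}

# Evaluate the profiled objective at nonlinear parameters.
# theta = c(log tau (n), shifts (n_curves, if fit_shift)).
# Returns weighted residual vector (concatenated fit ranges) plus the
# profiled linear parameters and expectations.
eval_global <- function(theta, prep) {
  n <- prep$n_components
  tau <- exp(theta[seq_len(n)])
  shifts <- if (prep$fit_shift)
    theta[n + seq_len(prep$n_curves)] else rep(0, prep$n_curves)
  res <- vector("list", prep$n_curves)
  alpha <- matrix(0, n, prep$n_curves)
  bg <- numeric(prep$n_curves)
  mu_list <- vector("list", prep$n_curves)
  for (j in seq_len(prep$n_curves)) {
    p <- shift_histogram(prep$irf_norm, shifts[j])
    B <- matrix(0, prep$n_bins, n)
    for (i in seq_len(n)) B[, i] <- conv_exp_irf(p, prep$dt, tau[i])
    rng <- prep$ranges[[j]]
    sol <- solve_linear_curve(B[rng, , drop = FALSE],
                              prep$counts[[j]][rng],
                              prep$weights[[j]][rng],
                              fit_background = prep$fit_background)
    alpha[, j] <- sol$alpha
    bg[j] <- sol$background
    mu <- drop(B %*% sol$alpha) + sol$background
    mu_list[[j]] <- mu
    res[[j]] <- sqrt(prep$weights[[j]][rng]) *
      (prep$counts[[j]][rng] - mu[rng])
  }
  list(residuals = unlist(res), tau = tau, shifts = shifts,
       alpha = alpha, background = bg, mu = mu_list)
}

# Levenberg-Marquardt on the profiled objective.
lm_minimize <- function(theta0, prep, reltol, maxit) {
  theta <- theta0
  ev <- eval_global(theta, prep)
  chisq <- sum(ev$residuals^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  stagnant <- 0L
  np <- length(theta)
  while (iter < maxit) {
    iter <- iter + 1L
    # forward-difference Jacobian of the weighted residuals
    J <- matrix(0, length(ev$residuals), np)
    for (k in seq_len(np)) {
      h <- 1e-6 * max(1, abs(theta[k]))
      th <- theta; th[k] <- th[k] + h
      J[, k] <- (eval_global(th, prep)$residuals - ev$residuals) / h
    }
    g <- crossprod(J, ev$residuals)       # = -1/2 grad chisq sign-wise
    H <- crossprod(J)
    dH <- diag(H)
    # a component whose profiled amplitude clamps to zero has an exactly
    # zero Jacobian column; floor its damping so the system stays
    # solvable and the live parameters can still take Gauss-Newton steps
    fl <- 1e-8 * max(dH, .Machine$double.xmin)
    dH[dH < fl] <- fl
    improved <- FALSE
    while (lambda <= 1e12) {
      step <- tryCatch(
        solve(H + lambda * diag(dH, nrow = np), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta - drop(step)   # J is d(residual)/d(theta) = -d(model)
        evc <- tryCatch(eval_global(cand, prep), error = function(e) NULL)
        if (!is.null(evc)) {
          cc <- sum(evc$residuals^2)
          if (is.finite(cc) && cc <= chisq) {
            rel <- (chisq - cc) / max(chisq, .Machine$double.xmin)
            theta <- cand; ev <- evc; chisq <- cc
            improved <- TRUE
            # a vanishing relative decrease signals convergence in the
            # near-Gauss-Newton regime; under heavy damping a single
            # micro-step does not, but repeated stagnation across
            # successive lambda reductions does (chi-square at its floor)
            if (rel < reltol) {
              stagnant <- stagnant + 1L
              if (lambda <= 1 || stagnant >= 3L) converged <- TRUE
            } else stagnant <- 0L
            lambda <- max(lambda / 10, 1e-12)
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # gradient-limited minimum
    if (converged) break
  }
  list(theta = theta, ev = ev, chisq = chisq, iterations = iter,
       converged = converged || iter < maxit)
}

#' Global fit of TCSPC decays by iterative reconvolution
#'
#' Fits `n_components` exponentials, reconvolved with the IRF, to one or
#' several decay curves simultaneously.  Lifetimes are common to all
#' curves; amplitudes, background and (optionally) an IRF channel shift
#' are free per curve.  Minimises the Poisson-weighted sum of squares
#' `sum w_k (C_k - M_k)^2` with Neyman weights `w_k = 1/max(C_k, 1)`.
#'
#' Lifetimes are optimised in log-space (positivity), profiled linear
#' parameters keep amplitudes non-negative, and components are sorted by
#' ascending lifetime on return.  If the iteration cap is reached the
#' result is returned with `converged = FALSE` rather than raising.
#'
#' @param curves a [decay_curve()] or list of them, all on the IRF grid.
#' @param irf the instrument response as a [decay_curve()].
#' @param n_components number of exponential components (1-6).
#' @param init optional [decay_model()] giving starting lifetimes (and,
#'   if complete, shifts); default initialisation is log-spaced lifetimes
#'   between 5 bin widths and a third of the window, equal amplitudes,
#'   zero shift.
#' @param fit_shift fit a per-curve IRF shift (default `TRUE`).
#' @param fit_background fit a per-curve constant background
#'   (default `TRUE`).
#' @param fit_range `NULL` for the per-curve [default_fit_range()], or an
#'   integer `c(first, last)` applied to every curve.
#' @param control list with `reltol` (relative chi-square change
#'   declaring convergence, default `1e-10`) and `maxit` (default 500).
#' @return object of class `global_fit_result`: converged
#'   [decay_model()], per-curve and global reduced chi-square, weighted
#'   residuals, runs-test p-values, fit ranges, iteration count and the
#'   per-curve fitted expectations.
#' @export
#' @examples
#' g <- make_time_grid(512, 25)
#' irf <- make_irf(irf_spec(80, 2), g)
#' d <- simulate_decay(decay_components(5, 1), irf, 1e4, seed = 7)
#' fit <- fit_global(d, irf, n_components = 1)
#' fit$model$lifetimes
fit_global <- function(curves, irf, n_components, init = NULL,
                       fit_shift = TRUE, fit_background = TRUE,
                       fit_range = NULL, control = list()) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  if (!length(curves)) abort_config("need at least one decay curve")
  if (!is.numeric(n_components) || n_components < 1 || n_components > 6 ||
      n_components != round(n_components))
    abort_config("n_components must be an integer in 1..6")
  for (cv in curves) check_same_grid(cv, irf, "data and IRF")
  if (all(vapply(curves, function(cv) all(cv$counts == 0), TRUE)))
    abort_data("all curves have zero counts: nothing to fit")
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 500L), control)

  n <- as.integer(n_components)
  nc <- length(curves)
  dt <- bin_width(irf)
  nb <- length(irf$times)
  ranges <- lapply(curves, function(cv) {
    r <- if (is.null(fit_range)) default_fit_range(cv, irf)
         else as.integer(fit_range)
    seq.int(r[1], r[2])
  })
  prep <- list(
    n_components = n, n_curves = nc, n_bins = nb, dt = dt,
    irf_norm = irf$counts / sum(irf$counts),
    counts = lapply(curves, `[[`, "counts"),
    weights = lapply(curves, function(cv) poisson_weights(cv$counts)),
    ranges = ranges, fit_shift = fit_shift,
    fit_background = fit_background)

  if (is.null(init)) {
    window <- nb * dt
    tau0 <- exp(seq(log(5 * dt), log(window / 3), length.out = max(n, 2)))[seq_len(n)]
    if (n == 1L) tau0 <- sqrt(5 * dt * window / 3)
    shifts0 <- numeric(nc)
  } else {
    if (!inherits(init, "decay_model")) abort_config("init must be a decay_model")
    if (init$n_components != n)
      abort_config("init has the wrong number of components")
    tau0 <- init$lifetimes
    shifts0 <- if (length(init$shift) == nc) init$shift else numeric(nc)
  }
  theta0 <- c(log(tau0), if (fit_shift) shifts0)

  opt <- lm_minimize(theta0, prep, ctrl$reltol, as.integer(ctrl$maxit))
  ev <- opt$ev

  ord <- order(ev$tau)
  model <- decay_model(ev$tau[ord],
                       ev$alpha[ord, , drop = FALSE],
                       background = ev$background,
                       shift = ev$shifts)

  n_free_total <- n + nc * (n + fit_background + fit_shift)
  per_curve_free <- n + fit_background + fit_shift + n / nc
  chisq_curve <- numeric(nc)
  runs_p <- rep(NA_real_, nc)
  wres <- vector("list", nc)
  for (j in seq_len(nc)) {
    rng <- ranges[[j]]
    w <- prep$weights[[j]][rng]
    r <- sqrt(w) * (prep$counts[[j]][rng] - ev$mu[[j]][rng])
    wres[[j]] <- r
    dof <- length(rng) - per_curve_free
    chisq_curve[j] <- sum(r^2) / dof
    if (length(r) >= 20)
      runs_p[j] <- tryCatch(residual_randomness(r), error = function(e) NA_real_)
  }
  dof_global <- sum(lengths(ranges)) - n_free_total
  structure(
    list(model = model,
         chisq_reduced = list(per_curve = chisq_curve,
                              global = opt$chisq / dof_global),
         weighted_residuals = wres,
         residual_randomness = runs_p,
         uncertainties = NULL,
         fit_range = lapply(ranges, range),
         n_iterations = opt$iterations,
         converged = opt$converged,
         expectations = ev$mu,
         wavelengths = vapply(curves, `[[`, numeric(1), "wavelength"),
         curve_totals = vapply(seq_len(nc), function(j)
           sum(ev$mu[[j]] - ev$background[j]), numeric(1)),
         n_free_params = n_free_total),
    class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf(
    "<global_fit_result> %d component(s), %d curve(s), chi2_r(global) = %.4g, %s in %d iter\n",
    x$model$n_components, ncol(x$model$amplitudes),
    x$chisq_reduced$global,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(x$model)
  invisible(x)
}

# Fixed-lifetime fit: lifetimes (any number) held at given values,
# amplitudes >= 0 and background profiled per curve by weighted linear
# least squares.  Used by the mixture estimator, where the union of two
# reference lifetime sets can exceed the free-fit component cap.
fit_fixed_lifetimes <- function(curves, irf, lifetimes,
                                fit_background = TRUE) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  for (cv in curves) check_same_grid(cv, irf, "data and IRF")
  nc <- length(curves)
  nb <- length(irf$times)
  prep <- list(
    n_components = length(lifetimes), n_curves = nc, n_bins = nb,
    dt = bin_width(irf), irf_norm = irf$counts / sum(irf$counts),
    counts = lapply(curves, `[[`, "counts"),
    weights = lapply(curves, function(cv) poisson_weights(cv$counts)),
    ranges = lapply(curves, function(cv) {
      r <- default_fit_range(cv, irf); seq.int(r[1], r[2])
    }),
    fit_shift = FALSE, fit_background = fit_background)
  ev <- eval_global(log(lifetimes), prep)
  A <- ev$alpha
  csum <- colSums(A); csum[csum == 0] <- 1
  A <- sweep(A, 2, csum, "/")
  totals <- vapply(seq_len(nc), function(j)
    sum(ev$mu[[j]] - ev$background[j]), numeric(1))
  w <- if (sum(totals) > 0) totals / sum(totals) else rep(1 / nc, nc)
  list(lifetimes = lifetimes, alpha = ev$alpha, afactors = A,
       afactors_sample = drop(A %*% w), background = ev$background,
       expectations = ev$mu)
}

#' Fractional amplitudes of a converged fit
#'
#' Per-curve A factors (columns sum to 1), and optionally the per-sample
#' summary: the intensity-weighted average across curves, weighting each
#' curve by its total fitted decay counts.
#'
#' @param result a `global_fit_result`.
#' @param per_sample return the single averaged A vector instead of the
#'   per-curve matrix.
#' @return matrix (`n_components` x `n_curves`) or numeric vector.
#' @export
a_factors <- function(result, per_sample = FALSE) {
  A <- model_afactors(result$model)
  if (!per_sample) return(A)
  w <- result$curve_totals
  if (sum(w) <= 0) w <- rep(1, length(w))
  drop(A %*% (w / sum(w)))
}
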
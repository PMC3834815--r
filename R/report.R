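# Conformational-population reporting: translate decay parameters into
# stacking-environment classes and between-condition changes.  2AP decay
# kinetics report on base stacking, not hydrogen bonding, so all classes
# are stated as stacking environments.

#' Assign decay components to stacking classes
#'
#' The shortest 2AP lifetimes (~50 ps) arise from bases well stacked in
#' the helix (rapid inter-base electron-transfer quenching); the longest
#' (~10 ns) from extrahelical, unquenched 2AP; intermediates from
#' partially stacked forms.  Components are classed by lifetime:
#' `tau <= boundaries[1]` (default 0.15 ns) stacked;
#' `tau >= boundaries[3]` (default 5 ns) extrahelical; intermediates
#' split at `boundaries[2]` (default 1 ns) into fast/slow partially
#' stacked.  Populations are the per-sample A factors summed by class.
#'
#' @param result a converged `global_fit_result` with 3 or 4 components.
#' @param boundaries numeric `c(stacked_max, partial_split, extrahelical_min)`
#'   in ns.
#' @return object of class `state_report`: per-component classes, class
#'   populations (sum to 1), lifetimes and per-sample A factors.
#' @export
classify_components <- function(result, boundaries = c(0.15, 1, 5)) {
  if (!inherits(result, "global_fit_result"))
    abort_config("result must be a global_fit_result")
  if (!result$converged)
    abort_state("refusing to classify an unconverged fit")
  n <- result$model$n_components
  if (n < 3 || n > 4)
    abort_config("classification expects a 3- or 4-component fit")
  tau <- result$model$lifetimes
  A <- a_factors(result, per_sample = TRUE)
  cls <- ifelse(tau <= boundaries[1], "stacked",
         ifelse(tau >= boundaries[3], "extrahelical",
         ifelse(tau < boundaries[2], "partially_stacked_fast",
                "partially_stacked_slow")))
  lv <- c("stacked", "partially_stacked_fast",
          "partially_stacked_slow", "extrahelical")
  pop <- vapply(lv, function(l) sum(A[cls == l]), numeric(1))
  structure(list(component_class = cls, populations = pop,
                 lifetimes = tau, afactors = A,
                 boundaries = boundaries),
            class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat("<state_report>\n")
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  tau%d = %8.4g ns  A = %.3f  %s\n", i, x$lifetimes[i],
                x$afactors[i], x$component_class[i]))
  cat("  populations:",
      paste(sprintf("%s = %.3f", names(x$populations), x$populations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Percentage change of decay parameters between conditions
#'
#' For components 1-3 matched by ascending-lifetime rank, computes
#' `100 * (X_sample - X_ref) / X_ref` for each lifetime and per-sample
#' A factor — the duplex-versus-single-strand "unpairing fingerprint"
#' representation.  Component 4, always a minor fraction, is omitted.
#'
#' @param sample,reference converged `global_fit_result`s with at least
#'   three components each.
#' @param n_report number of components reported (default 3).
#' @return data.frame with columns `component`, `tau_sample_ns`,
#'   `tau_reference_ns`, `delta_tau_pct`, `a_sample`, `a_reference`,
#'   `delta_a_pct`.  An entry whose reference parameter is zero is
#'   undefined and reported as `NA`.
#' @export
percent_param_change <- function(sample, reference, n_report = 3L) {
  for (x in list(sample, reference))
    if (!inherits(x, "global_fit_result") || !x$converged)
      abort_config("sample and reference must be converged global_fit_results")
  if (sample$model$n_components < n_report ||
      reference$model$n_components < n_report)
    abort_config(sprintf("both fits need at least %d components", n_report))
  ts <- sample$model$lifetimes[seq_len(n_report)]
  tr <- reference$model$lifetimes[seq_len(n_report)]
  as <- a_factors(sample, per_sample = TRUE)[seq_len(n_report)]
  ar <- a_factors(reference, per_sample = TRUE)[seq_len(n_report)]
  # a zero reference makes the change undefined for that entry only
  data.frame(component = seq_len(n_report),
             tau_sample_ns = ts, tau_reference_ns = tr,
             delta_tau_pct = ifelse(tr == 0, NA_real_, 100 * (ts - tr) / tr),
             a_sample = as, a_reference = ar,
             delta_a_pct = ifelse(ar == 0, NA_real_, 100 * (as - ar) / ar))
}

# Merge two lifetime sets, coalescing values closer than rel_tol, and
# return the union plus index maps from each input set into the union.
union_lifetimes <- function(tau_a, tau_b, rel_tol = 0.02) {
  all_tau <- sort(c(tau_a, tau_b))
  merged <- all_tau[1]
  for (t in all_tau[-1])
    if ((t - merged[length(merged)]) / merged[length(merged)] > rel_tol)
      merged <- c(merged, t)
  map <- function(tau) vapply(tau, function(t)
    which.min(abs(log(merged) - log(t))), integer(1))
  list(lifetimes = merged, map_a = map(tau_a), map_b = map(tau_b))
}

#' Estimate the paired/unpaired mixture fraction
#'
#' Treats the decay of a protein-DNA complex as a two-state mixture of a
#' paired (duplex-like) and an unpaired (single-strand-like) reference
#' state.  The complex curves are refitted with lifetimes fixed to the
#' union of the two reference lifetime sets (amplitudes and background
#' free, a linear problem), and the unpaired fraction `f` in `[0, 1]` is
#' the least-squares projection of the complex A vector onto the segment
#' between the duplex and single-strand reference A vectors embedded in
#' the union component space.
#'
#' @param complex_curves decay curve(s) of the complex.
#' @param ds_ref_result,ss_ref_result converged `global_fit_result`s of
#'   the paired (double-stranded) and unpaired (single-stranded)
#'   reference samples.
#' @param irf the IRF shared by all measurements.
#' @param rel_tol relative tolerance under which reference lifetimes are
#'   coalesced in the union.
#' @return list with `fraction` (in `[0, 1]`), `residual_distance`
#'   (Euclidean, A-vector units), the union lifetimes and the three A
#'   vectors in union space.
#' @export
estimate_mixture_fraction <- function(complex_curves, ds_ref_result,
                                      ss_ref_result, irf, rel_tol = 0.02) {
  for (x in list(ds_ref_result, ss_ref_result))
    if (!inherits(x, "global_fit_result") || !x$converged)
      abort_state("reference fits must be converged global_fit_results")
  u <- union_lifetimes(ds_ref_result$model$lifetimes,
                       ss_ref_result$model$lifetimes, rel_tol)
  k <- length(u$lifetimes)
  embed <- function(A, map) {
    v <- numeric(k)
    for (i in seq_along(A)) v[map[i]] <- v[map[i]] + A[i]
    v
  }
  a_ds <- embed(a_factors(ds_ref_result, per_sample = TRUE), u$map_a)
  a_ss <- embed(a_factors(ss_ref_result, per_sample = TRUE), u$map_b)
  d <- a_ss - a_ds
  if (sqrt(sum(d^2)) < 1e-6)
    stop_stackprobe("stackprobe_mixture_error",
                    "reference A vectors are identical: mixture fraction unidentifiable")
  # fixed-lifetime refit of the complex: purely linear in the amplitudes
  fit <- fit_fixed_lifetimes(complex_curves, irf, u$lifetimes)
  a_c <- fit$afactors_sample
  f <- sum((a_c - a_ds) * d) / sum(d^2)
  f <- min(1, max(0, f))
  resid <- sqrt(sum((a_c - (f * a_ss + (1 - f) * a_ds))^2))
  list(fraction = f, residual_distance = resid,
       union_lifetimes = u$lifetimes,
       a_complex = a_c, a_ds = a_ds, a_ss = a_ss)
}

#' Euclidean distance between decay-parameter sets
#'
#' Distance on the concatenation of the first `n_use` A factors and
#' log-lifetimes of two fits (rank-matched by ascending lifetime):
#' `sqrt(sum (A_a - A_b)^2 + sum (log tau_a - log tau_b)^2)`.  Used to
#' ask which reference state (duplex or single strand) a complex most
#' resembles.
#'
#' @param a,b `global_fit_result`s, or lists with elements `lifetimes`
#'   and `afactors`.
#' @param n_use number of leading components compared (default 3).
#' @return non-negative scalar; zero iff the compared parameters match.
#' @export
parameter_distance <- function(a, b, n_use = 3L) {
  get_set <- function(x) {
    if (inherits(x, "global_fit_result"))
      list(lifetimes = x$model$lifetimes,
           afactors = a_factors(x, per_sample = TRUE))
    else x
  }
  a <- get_set(a); b <- get_set(b)
  if (length(a$lifetimes) != length(b$lifetimes))
    abort_config("parameter sets have different component counts")
  if (length(a$lifetimes) < n_use)
    abort_config(sprintf("need at least %d components", n_use))
  i <- seq_len(n_use)
  sqrt(sum((a$afactors[i] - b$afactors[i])^2) +
       sum((log(a$lifetimes[i]) - log(b$lifetimes[i]))^2))
}
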
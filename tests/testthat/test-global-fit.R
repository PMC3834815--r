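# global iterative-reconvolution fitting

test_that("a noiseless single exponential is recovered to machine precision", {
  irf <- small_irf()
  cv <- noiseless_curve(decay_components(5, 1), irf)
  fit <- fit_global(cv, irf, 1)
  expect_true(fit$converged)
  expect_equal(fit$model$lifetimes, 5, tolerance = 1e-6)
  expect_lt(fit$chisq_reduced$global, 1e-12)
  expect_equal(sum(a_factors(fit)), 1, tolerance = 1e-9)
})

test_that("three-wavelength duplex data recovers all parameters within 10%", {
  irf <- small_irf()
  comp <- get_preset("duplex")
  set <- simulate_global_set(comp, irf, c(370, 380, 390), 1e4, seed = 31)
  fit <- fit_global(set, irf, 4)
  expect_true(fit$converged)
  expect_true(all(abs(fit$model$lifetimes - comp$lifetimes) /
                    comp$lifetimes <= 0.10))
  A <- a_factors(fit)
  truth <- comp$afactors[[1]]
  for (j in 1:3) {
    expect_true(all(abs(A[, j] - truth) / truth <= 0.10))
    expect_equal(sum(A[, j]), 1, tolerance = 1e-9)
  }
  # per-sample summary is an intensity-weighted average of the columns
  As <- a_factors(fit, per_sample = TRUE)
  expect_equal(sum(As), 1, tolerance = 1e-9)
  expect_true(all(As >= apply(A, 1, min) - 1e-12 &
                    As <= apply(A, 1, max) + 1e-12))
})

test_that("underfitting leaves a materially worse chi-square", {
  irf <- small_irf()
  set <- simulate_global_set(get_preset("duplex"), irf, 380, 1e4, seed = 13)
  fit2 <- fit_global(set, irf, 2)
  fit4 <- fit_global(set, irf, 4)
  expect_gt(fit2$chisq_reduced$global, 3 * fit4$chisq_reduced$global)
})

test_that("recovered parameters are invariant to rescaling the counts", {
  irf <- small_irf()
  comp <- decay_components(c(0.3, 3), c(0.6, 0.4))
  mu <- decay_expectation(comp, irf, 1e4)
  f1 <- fit_global(decay_curve(irf$times, mu), irf, 2)
  f3 <- fit_global(decay_curve(irf$times, 3 * mu), irf, 2)
  expect_equal(f1$model$lifetimes, f3$model$lifetimes, tolerance = 1e-6)
  expect_equal(a_factors(f1), a_factors(f3), tolerance = 1e-6)
})

test_that("fit_global rejects degenerate inputs", {
  irf <- small_irf()
  zero <- decay_curve(irf$times, numeric(length(irf$times)))
  expect_error(fit_global(zero, irf, 2), class = "stackprobe_data_error")
  cv <- noiseless_curve(decay_components(5, 1), irf)
  expect_error(fit_global(cv, irf, 0), class = "stackprobe_config_error")
  expect_error(fit_global(cv, irf, 7), class = "stackprobe_config_error")
  bad_grid <- decay_curve(make_time_grid(512, 25), numeric(512) + 1)
  expect_error(fit_global(bad_grid, irf, 1), class = "stackprobe_grid_error")
})

test_that("reduced_chisq implements Poisson-weighted least squares", {
  counts <- c(rep(100, 50), rep(10, 50))
  expect_equal(reduced_chisq(counts, counts, 0), 0)
  expect_error(reduced_chisq(counts, counts, length(counts)),
               class = "stackprobe_config_error")   # dof = 0
  # hand-computed: one bin off by d with Neyman weight 1/C
  mu <- counts; mu[1] <- 90
  expect_equal(reduced_chisq(counts, mu, 0), (10^2 / 100) / 100)

  # calibration against the true expectation over seeds
  irf <- small_irf()
  comp <- decay_components(3, 1)
  mu <- decay_expectation(comp, irf, 1e4)
  rng <- which(mu > 30)          # Neyman weighting is unbiased only for
  fr <- c(min(rng), max(rng))    # moderately populated bins
  vals <- vapply(1:10, function(s) {
    cv <- simulate_decay(comp, irf, 1e4, seed = 600 + s)
    reduced_chisq(cv, mu, 0, fit_range = fr)
  }, numeric(1))
  dof <- fr[2] - fr[1] + 1
  expect_true(all(abs(vals - 1) <= 3 * sqrt(2 / dof)))
})

test_that("residual_randomness is the two-sided Wald-Wolfowitz runs test", {
  alt <- rep(c(1, -1), 50)
  expect_lt(residual_randomness(alt), 1e-3)        # too regular
  expect_equal(residual_randomness(alt), runs_p_oracle(alt >= 0),
               tolerance = 1e-12)
  expect_equal(residual_randomness(rep(1, 30)), 0)  # one sign only
  expect_error(residual_randomness(rnorm(19)),
               class = "stackprobe_config_error")

  # i.i.d. residuals: p approximately uniform (KS over repeated draws)
  set.seed(99)
  ps <- vapply(1:200, function(i) residual_randomness(rnorm(500)), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-3)

  # blocked residuals (systematic misfit) are flagged
  set.seed(100)
  blocky <- rep(rnorm(25), each = 20)
  expect_lt(residual_randomness(blocky), 1e-6)
})

test_that("model-order selection finds simple truths and never overfits badly", {
  irf <- small_irf()
  one <- simulate_decay(decay_components(2, 1), irf, 1e4, seed = 3)
  expect_identical(as.integer(select_model_order(one, irf, 3)), 1L)

  two <- simulate_decay(decay_components(c(0.3, 4), c(0.5, 0.5)), irf, 1e4,
                        seed = 4)
  expect_identical(as.integer(select_model_order(two, irf, 4)), 2L)

  # starved of counts, the selector must stay at or below the truth
  comp4 <- get_preset("duplex")
  picks <- vapply(1:20, function(s) {
    d <- simulate_decay(comp4, irf, 100, seed = 5000 + s)
    as.integer(select_model_order(d, irf, max_components = 5))
  }, integer(1))
  expect_true(all(picks <= 4))
})

test_that("bootstrap uncertainties behave physically", {
  irf <- small_irf()
  comp <- get_preset("duplex")

  # "noiseless" limit: the parametric bootstrap always draws Poisson
  # noise around the fitted expectation, so uncertainties go to zero as
  # counts grow; at 1e8 peak counts they are negligible
  nl <- noiseless_curve(comp, irf)
  nl_big <- noiseless_curve(comp, irf, peak = 1e8)
  fit_big <- fit_global(nl_big, irf, 4)
  unc_big <- estimate_uncertainties(fit_big, list(nl_big), irf,
                                    n_boot = 5, seed = 1)
  expect_lt(max(unc_big$tau_rel_sd, unc_big$afactor_rel_sd), 1e-3)

  # 1e4 peak counts: every relative uncertainty within the 10% bound
  set <- simulate_global_set(comp, irf, c(370, 380, 390), 1e4, seed = 17)
  fit <- fit_global(set, irf, 4)
  unc <- estimate_uncertainties(fit, set, irf, n_boot = 12, seed = 2)
  expect_true(all(unc$tau_rel_sd <= 0.10))
  expect_true(all(unc$afactor_rel_sd <= 0.10))
  # determinism
  unc2 <- estimate_uncertainties(fit, set, irf, n_boot = 12, seed = 2)
  expect_identical(unc$tau_draws, unc2$tau_draws)

  # precision improves with counts (tau of a 2-component model)
  spread <- vapply(c(1e3, 1e5), function(pk) {
    comp2 <- decay_components(c(0.3, 3), c(0.6, 0.4))
    d <- simulate_decay(comp2, irf, pk, seed = 21)
    f <- fit_global(d, irf, 2)
    u <- estimate_uncertainties(f, list(d), irf, n_boot = 8, seed = 3)
    max(u$tau_rel_sd)
  }, numeric(1))
  expect_lt(spread[2], spread[1])

  fake <- fit_global(simulate_decay(comp, irf, 1e4, seed = 1), irf, 4)
  fake$converged <- FALSE
  expect_error(estimate_uncertainties(fake, list(nl), irf, 5, 1),
               class = "stackprobe_state_error")
})
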
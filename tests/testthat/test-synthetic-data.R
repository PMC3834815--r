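# synthetic decay / IRF / CD generators

test_that("make_time_grid produces the stated uniform grids and rejects bad input", {
  g <- make_time_grid(4096, 50)
  expect_length(g, 4096)
  expect_equal(g[2] - g[1], 50 / 4096)           # ~12.2 ps bins
  expect_equal(max(g), 50 - (50 / 4096) / 2)

  g2 <- make_time_grid(64, 6.4)
  expect_equal(unique(round(diff(g2), 12)), 0.1) # 64 bins of 100 ps

  expect_error(make_time_grid(0, 50), class = "stackprobe_config_error")
  expect_error(make_time_grid(4096, -1), class = "stackprobe_config_error")
  expect_error(make_time_grid(32, 50), class = "stackprobe_config_error")
})

test_that("make_irf discretizes to unit area with the requested peak and FWHM", {
  g <- make_time_grid(4096, 50)
  for (fwhm in c(80, 200)) {
    irf <- make_irf(irf_spec(fwhm, t0 = 2), g)
    expect_equal(sum(irf$counts), 1, tolerance = 1e-12)
    expect_true(all(irf$counts >= 0))
    # peak lands on the channel nearest t0
    expect_equal(which.max(irf$counts), which.min(abs(g - 2)))
    # numerically measured FWHM within one bin of the specification
    expect_equal(measure_fwhm(g, irf$counts), fwhm / 1e3,
                 tolerance = (g[2] - g[1]) / (fwhm / 1e3))
  }
  expect_error(make_irf(irf_spec(1e-4, 2), g),
               class = "stackprobe_config_error")   # below 0.1 bin widths
  expect_warning(make_irf(irf_spec(8e4, 25), g), "truncated")
  expect_error(make_irf(irf_spec(80, 200), g),
               class = "stackprobe_config_error")   # t0 outside the window
})

test_that("simulate_decay expectation is the IRF-convolved multi-exponential", {
  irf <- small_irf()
  g <- irf$times
  dt <- g[2] - g[1]
  # delta-like IRF: pure exponential tail with ratio e^-1 per lifetime
  di <- delta_irf(g)
  comp <- decay_components(10, 1)
  mu <- decay_expectation(comp, di, peak_counts = 1e4)
  k1 <- 200L
  k2 <- k1 + as.integer(round(10 / dt))
  expect_equal(mu[k2] / mu[k1], exp(-(g[k2] - g[k1]) / 10), tolerance = 1e-9)

  # brute-force O(N^2) convolution oracle
  comp4 <- get_preset("double_flap")
  mu4 <- decay_expectation(comp4, irf)
  oracle <- conv_direct_oracle(irf$counts / sum(irf$counts), dt,
                               comp4$lifetimes, comp4$afactors[[1]])
  expect_lt(max(abs(mu4 - oracle) / pmax(abs(oracle), 1e-300)), 1e-10)

  # linearity: two-component expectation = A-weighted sum of singles
  two <- decay_components(c(0.5, 5), c(0.3, 0.7))
  e_two <- decay_expectation(two, irf)
  e_a <- decay_expectation(decay_components(0.5, 1), irf)
  e_b <- decay_expectation(decay_components(5, 1), irf)
  expect_equal(e_two, 0.3 * e_a + 0.7 * e_b, tolerance = 1e-12)

  expect_error(decay_expectation(decay_components(1e-9, 1), irf),
               class = "stackprobe_config_error")  # lifetime < 1e-3 bins
  expect_error(simulate_decay(comp4, irf, peak_counts = 10),
               class = "stackprobe_config_error")
})

test_that("simulate_decay is seed-deterministic with Poisson-calibrated noise", {
  irf <- small_irf()
  comp <- get_preset("duplex")
  a <- simulate_decay(comp, irf, 1e4, seed = 1)
  b <- simulate_decay(comp, irf, 1e4, seed = 1)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts,
                         simulate_decay(comp, irf, 1e4, seed = 2)$counts))
  expect_true(all(a$counts == round(a$counts)))

  # Poisson property: sample mean at chosen bins converges to mu
  mu <- decay_expectation(comp, irf, 1e4)
  bins <- c(100L, 180L, 400L, 900L)
  n_seeds <- 200
  draws <- vapply(seq_len(n_seeds), function(s)
    simulate_decay(comp, irf, 1e4, seed = 1000 + s)$counts[bins],
    numeric(length(bins)))
  m <- rowMeans(draws)
  expect_true(all(abs(m - mu[bins]) <= 3 * sqrt(mu[bins] / n_seeds)))
})

test_that("simulate_global_set links lifetimes and separates noise streams", {
  irf <- small_irf()
  comp <- get_preset("double_flap")
  set <- simulate_global_set(comp, irf, c(370, 380, 390), 1e4, seed = 5)
  expect_length(set, 3)
  expect_equal(vapply(set, `[[`, numeric(1), "wavelength"), c(370, 380, 390))
  # shared A-list: identical expectations; different substreams: different counts
  expect_false(identical(set[[1]]$counts, set[[2]]$counts))

  # per-wavelength A-lists give differently shaped expectations
  comp2 <- decay_components(c(0.5, 5),
                            list(c(0.2, 0.8), c(0.8, 0.2)))
  e1 <- decay_expectation(comp2, irf, peak_counts = 1e4,
                          afactors = comp2$afactors[[1]])
  e2 <- decay_expectation(comp2, irf, peak_counts = 1e4,
                          afactors = comp2$afactors[[2]])
  keep <- e1 > 1 & e2 > 1
  r <- e1[keep] / e2[keep]
  expect_gt(max(r) / min(r), 2)   # not proportional

  # master seeds s and s+1: identical expectations, different counts
  s1 <- simulate_global_set(comp, irf, 380, 1e4, seed = 7)[[1]]
  s2 <- simulate_global_set(comp, irf, 380, 1e4, seed = 8)[[1]]
  expect_false(identical(s1$counts, s2$counts))

  expect_error(simulate_global_set(comp, irf, numeric(0), 1e4, seed = 1),
               class = "stackprobe_config_error")
})

test_that("preset library entries satisfy the component invariants", {
  lib <- preset_library()
  expect_true(all(c("duplex", "double_flap", "y40a_substrate",
                    "y40a_product", "single_strand") %in% names(lib)))
  for (nm in names(lib)) {
    comp <- lib[[nm]]$components
    expect_s3_class(comp, "decay_components")
    expect_true(all(diff(comp$lifetimes) > 0))
    for (a in comp$afactors) {
      expect_true(all(a >= 0))
      expect_equal(sum(a), 1, tolerance = 1e-9)
    }
  }
  # landmark values
  expect_equal(lib$duplex$components$afactors[[1]][1], 0.85)
  expect_equal(lib$double_flap$components$afactors[[1]][1:3],
               c(0.75, 0.17, 0.06))
  expect_equal(lib$double_flap$components$lifetimes[1:2], c(0.06, 0.3))
  expect_equal(lib$y40a_substrate$components$afactors[[1]][1:3],
               c(0.58, 0.30, 0.10))
  expect_equal(lib$y40a_product$components$afactors[[1]][4], 0.40)
  expect_equal(lib$y40a_product$components$lifetimes[4], 9)
  expect_equal(lib$y40a_product$components$afactors[[1]][1], 0.18)
  expect_error(get_preset("nope"), class = "stackprobe_config_error")
})

test_that("simulate_cd_spectrum follows the mixture rule on the 300-480 nm grid", {
  # fully unpaired, no baseline, no noise: identically zero
  z <- simulate_cd_spectrum(cd_couplet_spec(unpaired_fraction = 1), seed = 1)
  expect_true(all(z$values == 0))

  # mixture linearity (noiseless, baseline-free): s(f) = (1-f) * s(0)
  s0 <- simulate_cd_spectrum(cd_couplet_spec(unpaired_fraction = 0), seed = 1)
  s83 <- simulate_cd_spectrum(cd_couplet_spec(unpaired_fraction = 0.83), seed = 1)
  expect_equal(s83$values, 0.17 * s0$values, tolerance = 1e-12)
  i330 <- which(s0$wavelengths == 330)
  expect_equal(s83$values[i330] / s0$values[i330], 0.17, tolerance = 1e-12)

  # red-lobe peak lands at the configured centre within half a step
  pk <- s0$wavelengths[which.max(abs(s0$values))]
  expect_lte(abs(pk - 326), 0.5)

  # seeded noise is reproducible
  n1 <- simulate_cd_spectrum(cd_couplet_spec(noise_sd = 0.2), seed = 9)
  n2 <- simulate_cd_spectrum(cd_couplet_spec(noise_sd = 0.2), seed = 9)
  expect_identical(n1$values, n2$values)

  expect_error(simulate_cd_spectrum(cd_couplet_spec(), grid = seq(250, 480, 0.5)),
               class = "stackprobe_config_error")
  expect_error(cd_couplet_spec(unpaired_fraction = 1.2),
               class = "stackprobe_config_error")
  expect_error(cd_couplet_spec(lobe_amplitudes = c(2, 4)),
               class = "stackprobe_config_error")
})
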
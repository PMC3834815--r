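# CD processing chain

mk_spec <- function(values, units = "delta_epsilon", n_scans = 1L) {
  cd_spectrum(cd_default_grid_local(), values, units = units,
              n_scans = n_scans)
}
cd_default_grid_local <- function() seq(300, 480, by = 0.5)

test_that("average_scans is the pointwise mean with scan bookkeeping", {
  g <- cd_default_grid_local()
  a <- mk_spec(rep(1, length(g)))
  b <- mk_spec(rep(-1, length(g)))
  five <- average_scans(rep(list(a), 5))
  expect_equal(five$values, a$values)
  expect_identical(five$n_scans, 5L)
  expect_true(all(average_scans(list(a, b))$values == 0))

  # noise shrinks ~ 1/sqrt(5)
  spec <- cd_couplet_spec(noise_sd = 0.2)
  avg <- average_scans(lapply(1:5, function(s)
    simulate_cd_spectrum(spec, seed = 100 + s)))
  truth <- simulate_cd_spectrum(cd_couplet_spec(noise_sd = 0), seed = 1)
  expect_equal(stats::sd(avg$values - truth$values), 0.2 / sqrt(5),
               tolerance = 0.2)

  g2 <- seq(300, 400, 0.5)
  other <- cd_spectrum(g2, numeric(length(g2)), units = "delta_epsilon")
  expect_error(average_scans(list(a, other)), class = "stackprobe_grid_error")
  expect_error(average_scans(list(a, mk_spec(rep(1, length(g)), "mdeg"))),
               class = "stackprobe_config_error")
})

test_that("baseline_subtract removes a known blank exactly", {
  spec0 <- cd_couplet_spec(baseline_coeffs = c(0.5, -0.3, 0.2))
  samp <- simulate_cd_spectrum(spec0, seed = 1)
  blank <- simulate_cd_spectrum(
    cd_couplet_spec(unpaired_fraction = 1,
                    baseline_coeffs = c(0.5, -0.3, 0.2)), seed = 2)
  pure <- simulate_cd_spectrum(cd_couplet_spec(), seed = 3)
  corrected <- baseline_subtract(samp, blank)
  expect_equal(corrected$values, pure$values, tolerance = 1e-12)
  expect_equal(baseline_subtract(samp, samp)$values,
               numeric(length(samp$values)))
  expect_error(
    baseline_subtract(samp, mk_spec(rep(0, 361), units = "mdeg")),
    class = "stackprobe_config_error")
})

test_that("Means-Movement smoothing is a shrinking-window moving average", {
  g <- cd_default_grid_local()
  n <- length(g)
  const <- mk_spec(rep(3.7, n))
  expect_equal(smooth_means_movement(const, 5)$values, rep(3.7, n))

  spike <- numeric(n); spike[180] <- 10
  sm <- smooth_means_movement(mk_spec(spike), 5)
  expect_equal(sm$values[178:182], rep(2, 5))
  expect_equal(sum(sm$values), 10)           # interior mass conserved

  ramp <- mk_spec(seq(0, 1, length.out = n))
  smr <- smooth_means_movement(ramp, 5)
  expect_equal(smr$values[3:(n - 2)], ramp$values[3:(n - 2)],
               tolerance = 1e-12)
  # edge handling: endpoints untouched, neighbours use window 3
  expect_identical(smr$values[1], ramp$values[1])
  expect_equal(smr$values[2], mean(ramp$values[1:3]))

  # compactly supported signal (zero within 2 points of either edge):
  # the full-width windows redistribute each value with weight 1/5, so
  # the total — hence the interior mean — is conserved exactly
  set.seed(8)
  compact <- numeric(n)
  compact[50:300] <- rnorm(251)
  smc <- smooth_means_movement(mk_spec(compact), 5)
  expect_equal(sum(smc$values), sum(compact), tolerance = 1e-12)

  expect_error(smooth_means_movement(const, 4),
               class = "stackprobe_config_error")
})

test_that("mdeg <-> delta-epsilon conversion uses the 32980 relation", {
  # theta = 32980 * de * c * l: at 10 uM 2AP residues in a 1 cm cell,
  # delta-epsilon 0.1 corresponds to 32980 * 0.1 * 1e-5 = 0.03298 mdeg
  n <- length(cd_default_grid_local())
  theta <- mk_spec(rep(0.03298, n), units = "mdeg")
  de <- to_delta_epsilon(theta, conc_2AP = 10e-6, pathlength = 1)
  expect_equal(de$values, rep(0.1, n), tolerance = 1e-12)
  expect_identical(de$units, "delta_epsilon")
  # twice the 2AP residues per strand halves delta-epsilon
  de2 <- to_delta_epsilon(theta, conc_2AP = 20e-6, pathlength = 1)
  expect_equal(de2$values, de$values / 2, tolerance = 1e-12)
  # round trip
  back <- to_millidegrees(de, conc_2AP = 10e-6, pathlength = 1)
  expect_equal(back$values, theta$values, tolerance = 1e-12)
  expect_error(to_delta_epsilon(theta, conc_2AP = 0),
               class = "stackprobe_config_error")
  expect_error(to_delta_epsilon(de, conc_2AP = 1e-5),
               class = "stackprobe_config_error")
})

test_that("exciton_metrics reads the red band correctly", {
  z <- mk_spec(numeric(361))
  mz <- exciton_metrics(z)
  expect_equal(mz$amplitude_330, 0)
  expect_false(mz$peak_defined)
  expect_true(is.na(mz$peak_wavelength))

  lobe <- simulate_cd_spectrum(cd_couplet_spec(), seed = 1)
  m <- exciton_metrics(lobe)
  expect_lte(abs(m$peak_wavelength - 326), 0.5)
  expect_equal(m$amplitude_330, lobe$values[lobe$wavelengths == 330])
  expect_equal(m$band_mean_320_330,
               mean(lobe$values[lobe$wavelengths >= 320 &
                                  lobe$wavelengths <= 330]))
  g2 <- seq(340, 480, 0.5)
  high <- cd_spectrum(g2, rep(1, length(g2)), units = "delta_epsilon")
  expect_error(exciton_metrics(high), class = "stackprobe_config_error")
})

test_that("percent_signal_change follows the reduction convention", {
  lobe <- exciton_metrics(simulate_cd_spectrum(cd_couplet_spec(), seed = 1))
  expect_equal(percent_signal_change(lobe, lobe), 0)
  damp <- lobe; damp$amplitude_330 <- 0.17 * lobe$amplitude_330
  expect_equal(percent_signal_change(damp, lobe), 83, tolerance = 1e-9)
  # monotone decreasing in sample amplitude
  amps <- seq(0, 2, 0.25)
  pcs <- vapply(amps, function(a) {
    s <- lobe; s$amplitude_330 <- a
    percent_signal_change(s, lobe)
  }, numeric(1))
  expect_true(all(diff(pcs) < 0))
  zero <- lobe; zero$amplitude_330 <- 0
  expect_error(percent_signal_change(lobe, zero),
               class = "stackprobe_reference_error")
})

test_that("the full chain is linear and recovers the unpaired fraction", {
  # linearity: chain(a + b) = chain(a) + chain(b)
  chain <- function(s, blank) to_delta_epsilon(
    smooth_means_movement(baseline_subtract(s, blank), 5),
    conc_2AP = 2e-5)
  a <- to_millidegrees(simulate_cd_spectrum(cd_couplet_spec(noise_sd = 0.1),
                                            seed = 1), 2e-5)
  b <- to_millidegrees(simulate_cd_spectrum(
    cd_couplet_spec(lobe_centers = c(280, 315), noise_sd = 0.1), seed = 2), 2e-5)
  zero <- cd_spectrum(a$wavelengths, numeric(length(a$wavelengths)),
                      units = "mdeg", spacing = NULL)
  ab <- a; ab$values <- a$values + b$values
  expect_equal(chain(ab, zero)$values,
               chain(a, zero)$values + chain(b, zero)$values,
               tolerance = 1e-12)

  # end-to-end: 5-scan average, blank subtraction, smoothing, conversion;
  # noise 5% of the lobe amplitude
  conc <- 2e-5
  run_condition <- function(f, tag) {
    spec <- cd_couplet_spec(unpaired_fraction = f, noise_sd = 0.2,
                            baseline_coeffs = c(0.3, -0.2))
    bl <- cd_couplet_spec(unpaired_fraction = 1, noise_sd = 0.2,
                          baseline_coeffs = c(0.3, -0.2))
    scans <- lapply(1:5, function(s) to_millidegrees(
      simulate_cd_spectrum(spec, seed = substream_seed(1, paste0(tag, s))),
      conc))
    blanks <- lapply(1:5, function(s) to_millidegrees(
      simulate_cd_spectrum(bl, seed = substream_seed(1, paste0(tag, "b", s))),
      conc))
    exciton_metrics(to_delta_epsilon(smooth_means_movement(
      baseline_subtract(average_scans(scans), average_scans(blanks)), 5),
      conc))
  }
  ref <- run_condition(0, "ref")
  m51 <- run_condition(0.51, "s51")
  expect_lte(abs(percent_signal_change(m51, ref) - 51), 3)
})
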
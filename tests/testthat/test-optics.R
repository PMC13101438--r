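# Spectral-focusing CARS pulse and spectrum calculations.

test_that("Raman shift targets the CH2 stretch from the 805/1045 pair", {
  expect_equal(raman_shift(805, 1045), 2852.98, tolerance = 1e-4)
  expect_lt(abs(raman_shift(805, 1045) - 2845) / 2845, 0.005)
  expect_equal(raman_shift(900, 900), 0)
  shifts <- sapply(c(1000, 1020, 1045, 1100), raman_shift, pump_nm = 805)
  expect_true(all(diff(shifts) > 0))
  expect_error(raman_shift(1045, 805), "stokes")
})

test_that("transform-limited durations match the published bandwidths", {
  expect_equal(transform_limited_duration(9.0, 805), 105, tolerance = 0.02)
  expect_equal(transform_limited_duration(7.3, 1045), 220, tolerance = 0.02)
  # inverse proportionality in bandwidth
  expect_equal(transform_limited_duration(4.5, 805) /
               transform_limited_duration(9.0, 805), 2)
})

test_that("glass-rod GDD matches the unit-converted closed form", {
  gdd <- group_delay_dispersion(103, 19.6, 805)
  expect_lt(gdd, 0)  # negative chirp by default
  # dimensional-analysis oracle, SI throughout
  D_si <- 103e-12 / (1e-9 * 1e3)
  phi2_si <- D_si * (805e-9)^2 * 0.196 / (2 * pi * 299792458)
  expect_equal(abs(gdd), phi2_si * 1e30, tolerance = 1e-12)
  expect_equal(abs(gdd), 6.9e3, tolerance = 0.01)
  expect_equal(group_delay_dispersion(103, 0, 805), 0)
  expect_equal(group_delay_dispersion(103, 39.2, 805), 2 * gdd)
})

test_that("Gaussian chirp stretching behaves as the closed form requires", {
  expect_equal(chirped_duration(105, 0)$stretch_factor, 1.0)
  # published rod parameters stretch the pump by ~2x under this law
  gdd <- abs(group_delay_dispersion(103, 19.6, 805))
  f <- chirped_duration(105.9, gdd)$stretch_factor
  expect_equal(f, 2.0, tolerance = 0.02)
  # always >= transform limit, equality iff GDD = 0
  for (gg in c(1, 100, 5000, 5e4))
    expect_gt(chirped_duration(105, gg)$duration_fs, 105)
  # large-GDD asymptote: tau_out -> 4 ln2 |phi2| / tau
  tau <- 50; big <- 1e6
  expect_equal(chirped_duration(tau, big)$duration_fs,
               4 * log(2) * big / tau, tolerance = 1e-4)
})

test_that("chirp law agrees with numerical spectral-phase propagation", {
  # independent oracle: add quadratic spectral phase to a Gaussian field and
  # measure the output intensity FWHM on a dense numeric grid
  tau <- 105; gdd <- 6945
  t <- seq(-3000, 3000, length.out = 16384)
  dt <- t[2] - t[1]
  field <- exp(-2 * log(2) * t^2 / tau^2)  # field envelope, intensity FWHM tau
  w <- 2 * pi * c(seq(0, length(t) / 2 - 1), seq(-length(t) / 2, -1)) /
    (length(t) * dt)
  spec <- fft(field) * exp(1i * gdd / 2 * w^2)
  out <- abs(fft(spec, inverse = TRUE))^2
  out <- out / max(out)
  ts <- t[order(t)]; os <- out[order(t)]
  above <- range(which(os >= 0.5))
  fwhm_num <- ts[above[2]] - ts[above[1]]
  expect_equal(chirped_duration(tau, gdd)$duration_fs, fwhm_num,
               tolerance = 0.005)
})

test_that("spectral FWHM recovers a synthetic Gaussian line", {
  wn <- seq(2600, 3300, by = 2)
  sigma <- 50
  spec <- data.frame(wavenumber = wn,
                     intensity = exp(-(wn - 2950)^2 / (2 * sigma^2)))
  fw <- spectral_fwhm(spec)
  expect_lt(abs(fw - 2 * sqrt(2 * log(2)) * sigma), 2)  # one grid step
  # constant offsets are removed by the baseline
  spec2 <- spec; spec2$intensity <- spec2$intensity + 5
  expect_equal(spectral_fwhm(spec2), fw, tolerance = 1e-6)
  # sloped baselines too
  spec3 <- spec; spec3$intensity <- spec3$intensity + 0.001 * wn
  expect_lt(abs(spectral_fwhm(spec3) - fw), 2)
  # narrower peaks give smaller FWHM
  spec4 <- data.frame(wavenumber = wn,
                      intensity = exp(-(wn - 2950)^2 / (2 * 25^2)))
  expect_lt(spectral_fwhm(spec4), fw)
  # non-peaked spectrum errors
  flat <- data.frame(wavenumber = wn, intensity = rep(1, length(wn)))
  expect_error(spectral_fwhm(flat), "peak|crossing")
})

test_that("spectrum files round-trip through the two-column text format", {
  wn <- seq(2700, 3200, by = 5)
  spec <- data.frame(wavenumber = wn,
                     intensity = exp(-(wn - 2900)^2 / (2 * 40^2)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(spec, f, row.names = FALSE)
  back <- read_spectrum(f)
  expect_equal(back$wavenumber, spec$wavenumber)
  expect_equal(spectral_fwhm(back, c(2750, 3050)),
               spectral_fwhm(spec, c(2750, 3050)))
})

test_that("delay scans are symmetric, peaked at zero, and widen as expected", {
  pump <- laser_pulse(805, spectral_fwhm = 9.0)
  stokes <- laser_pulse(1045, spectral_fwhm = 7.3)
  delays <- seq(-1500, 1500, by = 10)
  scan <- cross_correlation_scan(pump, pump, delays)
  expect_equal(scan$delay_fs[which.max(scan$intensity)], 0)
  expect_equal(scan$intensity, rev(scan$intensity), tolerance = 1e-9)
  # analytic Gaussian convolution oracle: I_p^2 has FWHM tau_p/sqrt(2);
  # the correlation FWHM is sqrt(tau_p^2/2 + tau_s^2)
  fine <- seq(-400, 400, by = 1)
  scan2 <- cross_correlation_scan(pump, stokes, fine)
  fwhm <- diff(range(scan2$delay_fs[scan2$intensity >= 0.5]))
  expect_equal(fwhm,
               sqrt(pump$duration_fwhm^2 / 2 + stokes$duration_fwhm^2),
               tolerance = 0.02)
  # chirped (stretched) pulses widen the scan
  sp <- laser_pulse(805, spectral_fwhm = 9.0, duration_fwhm = 250)
  ss <- laser_pulse(1045, spectral_fwhm = 7.3, duration_fwhm = 233)
  scan3 <- cross_correlation_scan(sp, ss, fine)
  w3 <- diff(range(scan3$delay_fs[scan3$intensity >= 0.5]))
  expect_gt(w3, fwhm)
  expect_error(cross_correlation_scan(pump, stokes, numeric(0)), "empty")
})

test_that("pulses below the transform limit are rejected", {
  expect_error(laser_pulse(805, spectral_fwhm = 9.0, duration_fwhm = 50),
               "transform limit")
  p <- laser_pulse(805, spectral_fwhm = 9.0)
  expect_equal(p$duration_fwhm, p$transform_limit)
})
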
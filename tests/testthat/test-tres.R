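flat_kinetics_dataset <- function(shape = c(1, 3, 2), n = 1e5, seed = 1) {
  # same lifetime everywhere; amplitudes proportional to `shape`
  irf <- make_irf(80)
  wl <- c(310, 330, 350)
  out <- lapply(seq_along(wl), function(i) {
    simulate_decay(fixture_model(2), irf,
                   n_photons = round(n * shape[i]), seed = seed + i,
                   emission_wavelength = wl[i])
  })
  stats::setNames(out, wl)
}

test_that("full-range integration recovers the steady-state shape", {
  d <- flat_kinetics_dataset()
  sp <- integrate_window(d, time_window(-1, 10.5))
  expect_equal(sp$intensity / max(sp$intensity), c(1, 3, 2) / 3,
               tolerance = 0.02)
})

test_that("a zero-signal window integrates to zero and out-of-grid errors", {
  d <- flat_kinetics_dataset()
  sp <- integrate_window(d, time_window(-1, -0.6))
  expect_lt(max(abs(sp$intensity)), 25)
  expect_error(integrate_window(d, time_window(9, 12)), "range error")
})

test_that("window integration is additive bin-exactly", {
  d <- flat_kinetics_dataset()
  ab <- integrate_window(d, time_window(-1, 1))$intensity
  bc <- integrate_window(d, time_window(1, 10.5))$intensity
  ac <- integrate_window(d, time_window(-1, 10.5))$intensity
  expect_equal(ab + bc, ac, tolerance = 1e-9)
})

test_that("response correction divides out the sensitivity", {
  sp <- data.frame(wavelength = c(310, 330, 350), intensity = c(2, 6, 4))
  unit <- response_curve(c(300, 360), c(1, 1))
  expect_equal(correct_response(sp, unit)$intensity, sp$intensity)
  self <- response_curve(sp$wavelength, sp$intensity)
  expect_equal(correct_response(sp, self)$intensity, rep(1, 3))
  # the generator's own distortion inverts exactly
  resp <- default_response_curve()
  sens <- stats::approx(resp$wavelengths, resp$sensitivity,
                        sp$wavelength)$y
  distorted <- transform(sp, intensity = intensity * sens)
  expect_equal(correct_response(distorted, resp)$intensity, sp$intensity,
               tolerance = 1e-9)
  neg <- response_curve(c(300, 360), c(1, 2))
  expect_error(correct_response(data.frame(wavelength = 280, intensity = 1),
                                neg), "cover")
})

test_that("TRES normalization peaks at 1 and is idempotent and scale invariant", {
  d <- flat_kinetics_dataset()
  tr <- build_tres(d, list(c(-1, 10.5)), default_response_curve())
  expect_equal(max(tr$spectra$normalized_intensity), 1)
  d10 <- lapply(d, function(x)
    decay_curve(x$grid, x$counts * 10L, x$emission_wavelength))
  tr10 <- build_tres(d10, list(c(-1, 10.5)), default_response_curve())
  expect_equal(tr$spectra$normalized_intensity,
               tr10$spectra$normalized_intensity, tolerance = 1e-9)
})

test_that("preset TRES reproduces the published window peaks", {
  preset <- get_preset("pApT", 267)
  decays <- simulate_preset_decays(preset, n_photons = 1e6, seed = 42)
  tres <- build_tres(decays, list(c(-0.05, 0.05), c(0.1, 1), c(1, 10)),
                     preset$response)
  peaks <- vapply(c(-0.05, 0.1, 1), function(lo) {
    sp <- tres$spectra[tres$spectra$window_lo_ns == lo, ]
    peak_wavelength(sp)$wavelength
  }, numeric(1))
  expect_lt(abs(peaks[1] - 330), 2.5)
  expect_lt(abs(peaks[2] - 320), 2.5)
  expect_lte(peaks[3], 305)
  # late-window visible photons are ~20% of the UV photons
  sp <- tres$spectra[tres$spectra$window_lo_ns == 1, ]
  vu <- sum(sp$intensity[sp$wavelength >= 410 & sp$wavelength <= 440]) /
    sum(sp$intensity[sp$wavelength >= 305 & sp$wavelength <= 400])
  expect_lt(abs(100 * vu - 20), 3)
})

test_that("photon budget percentages sum to 100 and merge additively", {
  d <- flat_kinetics_dataset()
  b3 <- photon_budget(d)
  expect_equal(sum(b3$percentage), 100, tolerance = 1e-6)
  b2 <- photon_budget(d, list(time_window(-1, 1), time_window(1, 10.5)))
  expect_equal(b2$percentage[1], b3$percentage[1] + b3$percentage[2],
               tolerance = 1e-9)
  b1 <- photon_budget(d, list(time_window(-1, 10.5)))
  expect_equal(b1$percentage, 100)
  expect_error(photon_budget(d, list(time_window(-1, 2),
                                     time_window(1, 10.5))),
               "partition")
  expect_error(photon_budget(d, list(time_window(-1, 1),
                                     time_window(2, 10.5))),
               "partition")
})

test_that("spectral FWHM in wavenumber matches the Gaussian closed form", {
  # Gaussian in wavenumber, sigma = 1000 cm^-1 -> FWHM 2354.8 cm^-1
  nu <- seq(24000, 36000, by = 10)
  sp <- steady_state_spectrum(rev(1e7 / nu),
                              rev(exp(-0.5 * ((nu - 30000) / 1000)^2)))
  expect_lt(abs(spectral_fwhm_wavenumber(sp) - 2 * sqrt(2 * log(2)) * 1000),
            1)
  # bimodal spectrum is rejected
  bim <- steady_state_spectrum(seq(300, 460, 2), {
    x <- seq(300, 460, 2)
    exp(-((x - 330) / 12)^2) + exp(-((x - 420) / 12)^2)
  })
  expect_error(spectral_fwhm_wavenumber(bim), "multimodal")
})

test_that("preset spectral widths are 5400 and 6900 wavenumbers", {
  sp_p <- simulate_steady_state_spectrum(get_preset("pApT", 285))
  sp_o <- simulate_steady_state_spectrum(get_preset("A20T20", 285))
  expect_lt(abs(spectral_fwhm_wavenumber(sp_p) - 5400), 50)
  expect_lt(abs(spectral_fwhm_wavenumber(sp_o) - 6900), 50)
})

test_that("peak interpolation refines a symmetric triangle and flags edges", {
  tri <- data.frame(wavelength = c(320, 325, 330, 335, 340),
                    intensity = c(0, 0.5, 1, 0.5, 0))
  expect_equal(peak_wavelength(tri)$wavelength, 330)
  mono <- data.frame(wavelength = c(320, 330, 340),
                     intensity = c(3, 2, 1))
  pk <- peak_wavelength(mono)
  expect_true(pk$edge)
  expect_equal(pk$wavelength, 320)
})
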
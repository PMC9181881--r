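test_that("unknown preset combinations are rejected", {
  expect_error(get_preset("A20T20", 267), "unknown preset")
  expect_error(get_preset("A20T20", 285, "diluted_6x"), "unknown preset")
  expect_error(get_preset("pGC", 267), "arg")
})

test_that("presets encode the published tail lifetimes and fractions", {
  p267 <- get_preset("pApT", 267)
  expect_equal(p267$targets$tau_long[match(305, p267$wavelengths)], 2.6)
  p285 <- get_preset("pApT", 285)
  expect_equal(p285$targets$tau_long[p285$wavelengths == 305], 2.2)
  expect_equal(p285$targets$f[p285$wavelengths == 305], 0.275)
  expect_equal(p285$targets$f[p285$wavelengths == 330], 0.125)
  a20 <- get_preset("A20T20", 285)
  expect_equal(a20$targets$tau_long[a20$wavelengths == 305], 2.7)
  expect_equal(a20$targets$f[a20$wavelengths == 305], 0.501)
  expect_equal(a20$targets$f[a20$wavelengths == 330], 0.306)
  dil <- get_preset("pApT", 285, "diluted_6x")
  expect_equal(dil$targets$f[dil$wavelengths == 305], 0.317)
  expect_equal(dil$targets$f[dil$wavelengths == 330], 0.157)
})

test_that("KCl-matched buffer shares the standard-buffer decay models", {
  std <- get_preset("pApT", 267, "standard")
  kcl <- get_preset("pApT", 267, "KCl_matched")
  expect_equal(kcl$decay_models[["305"]]$components,
               std$decay_models[["305"]]$components)
  expect_identical(kcl$buffer, "KCl_matched")
})

test_that("anisotropy plateaus are 0.02 for the polymer, 0.04 for the oligomer", {
  expect_equal(get_preset("pApT", 285)$anisotropy_models[["305"]]$r_inf, 0.02)
  expect_equal(get_preset("A20T20", 285)$anisotropy_models[["305"]]$r_inf,
               0.04)
})

test_that("calibration closure: noise-free analysis reproduces the targets", {
  for (args in list(list("pApT", 267, "standard"),
                    list("A20T20", 285, "standard"))) {
    preset <- do.call(get_preset, args)
    irf <- preset_irf(preset)
    for (wl in intersect(c(305, 420), preset$wavelengths)) {
      i <- match(wl, preset$wavelengths)
      mu <- expected_counts(preset$decay_models[[i]], irf,
                            include_background = FALSE)
      d <- decay_curve(preset$grid, round(mu * 1e8 / sum(mu)),
                       emission_wavelength = wl)
      f <- fraction_after(d, 1.0)
      expect_equal(f, preset$targets$f[i], tolerance = 0.01)
    }
  }
})

test_that("preset steady-state ratio is consistent with its generated spectrum", {
  for (sys in c("pApT", "A20T20")) {
    preset <- get_preset(sys, 285)
    sp <- simulate_steady_state_spectrum(preset)
    expect_equal(ss_intensity_ratio(sp), preset$ss_ratio_305_420,
                 tolerance = 0.05)
  }
})

test_that("decay models exist at the three canonical wavelengths", {
  for (args in list(list("pApT", 267), list("pApT", 285),
                    list("A20T20", 285))) {
    preset <- do.call(get_preset, args)
    expect_true(all(c("305", "330", "420") %in% names(preset$decay_models)))
    for (m in preset$decay_models)
      expect_gte(nrow(m$components), 4)
  }
})

test_that("preset decay models carry at least five lifetimes at 305 nm", {
  preset <- get_preset("pApT", 267)
  expect_gte(nrow(preset$decay_models[["305"]]$components), 5)
})

test_that("dataset simulation weights follow the measured spectrum", {
  preset <- get_preset("pApT", 267)
  decays <- simulate_preset_decays(preset, n_photons = 2e5, seed = 9)
  totals <- vapply(decays, function(d) sum(d$counts), numeric(1))
  expect_equal(unname(totals / max(totals)),
               preset$targets$weight / max(preset$targets$weight),
               tolerance = 0.05)
})
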
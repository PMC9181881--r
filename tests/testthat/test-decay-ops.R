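make_decay <- function(counts, grid = NULL) {
  if (is.null(grid)) grid <- time_grid(-1, -1 + 0.025 * length(counts), 0.025)
  decay_curve(grid, counts, emission_wavelength = 305)
}

test_that("background is the pre-rise mean and requires pre-rise bins", {
  g <- time_grid()
  counts <- integer(460); counts[1:20] <- 7L; counts[100] <- 50L
  expect_equal(estimate_background(make_decay(counts, g)), 7)

  # Poisson pre-rise: mean of 20 bins within 3 standard errors
  set.seed(1)
  counts2 <- integer(460); counts2[1:20] <- rpois(20, 5); counts2[100] <- 50L
  expect_lt(abs(estimate_background(make_decay(counts2, g)) - 5),
            3 * sqrt(5 / 20))

  g0 <- time_grid(0, 10.5, 0.025)
  expect_error(estimate_background(make_decay(rep(1L, 420), g0)),
               "insufficient baseline")
})

test_that("normalization subtracts background and peaks at exactly 1", {
  d <- make_decay(c(0L, 10L, 5L, rep(0L, 37)))
  expect_equal(normalize_decay(d, background = 0)[1:3], c(0, 1, 0.5))
  d2 <- make_decay(c(3L, 13L, 8L, rep(3L, 37)))
  expect_equal(normalize_decay(d2, background = 3)[1:3], c(0, 1, 0.5))
  # idempotence on the normalized vector
  n1 <- normalize_decay(d, background = 0)
  expect_equal(max(n1), 1)
  expect_equal(n1 / max(n1), n1)
  expect_error(normalize_decay(make_decay(rep(2L, 40)), background = 2),
               "degenerate")
})

test_that("fraction_after matches the closed form for a single exponential", {
  g <- time_grid()
  m <- fixture_model(2.6)
  d <- simulate_decay(m, make_irf(0, g, t0 = 0), 5e6, seed = 2)
  f <- fraction_after(d, 1.0)
  expect_equal(f, exp_fraction_after(2.6, 1, 10.5), tolerance = 2e-3)
  expect_equal(exp_fraction_after(2.6), 0.675, tolerance = 1e-3)

  # whole-window cut returns 1
  expect_equal(fraction_after(d, -0.999999), 1)
  expect_error(fraction_after(d, -1), "inside")
})

test_that("fraction_after is scale invariant and monotone in lifetime", {
  g <- time_grid()
  irf <- make_irf(0, g, t0 = 0)
  d <- simulate_decay(fixture_model(2.6), irf, 1e5, seed = 5)
  d10 <- decay_curve(g, d$counts * 10L, emission_wavelength = 305)
  expect_equal(fraction_after(d, 1), fraction_after(d10, 1), tolerance = 1e-12)

  taus <- c(0.5, 1, 2, 4, 8)
  fr <- vapply(taus, function(tau) {
    fraction_after(simulate_decay(fixture_model(tau), irf, 1e6, seed = 8))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("tail fit is exact for noise-free mono-exponential data", {
  g <- time_grid()
  mu <- expected_counts(fixture_model(2.0), make_irf(80, g),
                        include_background = FALSE)
  d <- decay_curve(g, round(mu * 1e7), emission_wavelength = 305)
  fit <- tail_fit(d)
  expect_equal(fit$tau, 2.0, tolerance = 5e-4)
  expect_gte(fit$background, 0)
})

test_that("tail fit agrees with the brute-force grid-search oracle", {
  g <- time_grid()
  m <- decay_model(data.frame(amplitude = c(2, 0.4),
                              lifetime = c(0.5, 2.5)))
  d <- simulate_decay(m, make_irf(80, g), 1e6, seed = 13)
  fit <- tail_fit(d)
  mask <- bin_centers(g) >= 1.5 & bin_centers(g) <= 10.5
  tau_oracle <- grid_search_tau(bin_centers(g)[mask],
                                as.numeric(d$counts[mask]))
  expect_equal(fit$tau, tau_oracle, tolerance = 0.01)
})

test_that("tail fit re-recovers its own parameters across seeds", {
  g <- time_grid()
  irf <- make_irf(80, g)
  base <- tail_fit(simulate_decay(fixture_model(2.6, background = 2),
                                  irf, 1e6, seed = 1))
  refit_model <- decay_model(
    data.frame(amplitude = base$amplitude * exp(1.5 / base$tau),
               lifetime = base$tau),
    background_rate = base$background)
  taus <- vapply(1:20, function(s) {
    tail_fit(simulate_decay(refit_model, irf, 1e6, seed = 100 + s))$tau
  }, numeric(1))
  se <- stats::sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - base$tau), 2 * se + 0.01)
})

test_that("tail fit rejects degenerate inputs", {
  g <- time_grid()
  d <- decay_curve(g, rep(3L, 460))
  expect_error(tail_fit(d), "degenerate")
  d2 <- simulate_decay(fixture_model(2.6), make_irf(80, g), 1e5, seed = 1)
  expect_error(tail_fit(d2, time_window(10.2, 10.5)), "20 bins")
})
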
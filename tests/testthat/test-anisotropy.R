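pair_from_r <- function(r, n_base = 6000, grid = time_grid()) {
  # constant-anisotropy pair with flat intensity and known background 0
  np <- as.integer(round(n_base * (1 + 2 * r) / 3))
  nq <- as.integer(round(n_base * (1 - r) / 3))
  counts_par <- integer(grid$n_bins); counts_perp <- integer(grid$n_bins)
  sig <- bin_centers(grid) > 0
  counts_par[sig] <- np; counts_perp[sig] <- nq
  list(par = decay_curve(grid, counts_par, 305, polarization = "parallel"),
       perp = decay_curve(grid, counts_perp, 305,
                          polarization = "perpendicular"))
}

test_that("anisotropy of equal channels is zero, 3:1 gives 0.4", {
  p0 <- pair_from_r(0)
  tr0 <- compute_r_trace(p0$par, p0$perp)
  expect_equal(tr0$r_values[tr0$defined], rep(0, sum(tr0$defined)))
  p4 <- pair_from_r(0.4)
  tr4 <- compute_r_trace(p4$par, p4$perp)
  expect_equal(unique(tr4$r_values[tr4$defined]), 0.4, tolerance = 1e-3)
})

test_that("r trace is invariant under common rescaling of both channels", {
  preset <- get_preset("pApT", 285)
  pair <- simulate_preset_pair(preset, 305, n_photons = 2e5, seed = 6)
  tr1 <- compute_r_trace(pair$parallel, pair$perpendicular)
  par10 <- decay_curve(pair$parallel$grid, pair$parallel$counts * 10L,
                       305, polarization = "parallel")
  perp10 <- decay_curve(pair$perpendicular$grid,
                        pair$perpendicular$counts * 10L, 305,
                        polarization = "perpendicular")
  tr10 <- compute_r_trace(par10, perp10)
  i <- which(tr1$defined & tr10$defined)
  expect_equal(tr1$r_values[i], tr10$r_values[i], tolerance = 1e-12)
})

test_that("magic-angle reconstruction is (par + 2 perp) / 3", {
  g <- time_grid(-1, 0, 0.025)
  par <- decay_curve(g, rep(3L, 40), polarization = "parallel")
  perp <- decay_curve(g, rep(1L, 40), polarization = "perpendicular")
  expect_equal(magic_from_pair(par, perp), rep(5 / 3, 40))
  iso <- decay_curve(g, rep(4L, 40), polarization = "perpendicular")
  expect_equal(magic_from_pair(iso, iso), as.numeric(iso$counts))
})

test_that("noise-free magic reconstruction equals the population decay", {
  preset <- get_preset("A20T20", 285)
  exp_pair <- expected_polarized_pair(preset$decay_models[["305"]],
                                      preset$anisotropy_models[["305"]],
                                      preset_irf(preset))
  magic <- (exp_pair$parallel + 2 * exp_pair$perpendicular) / 3
  expect_equal(magic, exp_pair$population / 3, tolerance = 1e-9)
})

test_that("single-angle anisotropy hits its closed-form landmarks", {
  expect_identical(theta_anisotropy(0), 0.4)
  expect_equal(theta_anisotropy(90), -0.2)
  expect_equal(theta_anisotropy(54.7356103), 0, tolerance = 1e-7)
  # full range is exactly [-0.2, 0.4]
  r <- theta_anisotropy(seq(0, 360, by = 0.1))
  expect_equal(range(r), c(-0.2, 0.4))
})

test_that("in-plane random model gives 0.1 by closed form, quadrature and Monte Carlo", {
  expect_identical(in_plane_limit(), 0.1)
  expect_equal(in_plane_limit("quadrature"), 0.1, tolerance = 1e-9)
  set.seed(42)
  theta <- runif(1e6, 0, 2 * pi)
  mc <- mean((3 * cos(theta)^2 - 1) / 5)
  se <- stats::sd((3 * cos(theta)^2 - 1) / 5) / 1000
  expect_lt(abs(mc - 0.1), 3 * se)
  # degenerate distribution at theta = 0 gives the parallel limit
  expect_identical(theta_anisotropy(0), 0.4)
})

test_that("plateau_r averages with inverse-variance weights", {
  p <- pair_from_r(0.02, n_base = 60000)
  tr <- compute_r_trace(p$par, p$perp)
  pl <- plateau_r(tr, time_window(2, 9))
  expect_equal(pl$r, 0.02, tolerance = 1e-3)
  expect_error(plateau_r(tr, time_window(-0.9, -0.6)), "insufficient")
})

test_that("anisotropy round trip recovers the model trace after the IRF settles", {
  preset <- get_preset("A20T20", 285)
  for (wl in c("305", "420")) {
    exp_pair <- expected_polarized_pair(preset$decay_models[[wl]],
                                        preset$anisotropy_models[[wl]],
                                        preset_irf(preset))
    r_rec <- (exp_pair$parallel - exp_pair$perpendicular) /
      (exp_pair$parallel + 2 * exp_pair$perpendicular)
    tc <- bin_centers(preset$grid)
    r_true <- eval_anisotropy(preset$anisotropy_models[[wl]], tc)
    late <- tc >= 0.5
    expect_lt(max(abs(r_rec[late] - r_true[late])), 5e-3)
  }
})

test_that("noisy round trip stays within propagated errors at most bins", {
  preset <- get_preset("pApT", 285)
  tc <- bin_centers(preset$grid)
  r_true <- eval_anisotropy(preset$anisotropy_models[["305"]], tc)
  late <- which(tc >= 0.5 & tc <= 9)
  cover <- vapply(1:10, function(s) {
    pair <- simulate_preset_pair(preset, 305, n_photons = 5e5, seed = s)
    tr <- compute_r_trace(pair$parallel, pair$perpendicular)
    i <- intersect(late, which(tr$defined))
    mean(abs(tr$r_values[i] - r_true[i]) <= 3 * tr$r_stderr[i])
  }, numeric(1))
  expect_gt(mean(cover), 0.95)
})

test_that("grid mismatch errors", {
  p <- pair_from_r(0.1)
  other <- decay_curve(time_grid(-1, 10, 0.025), integer(440),
                       polarization = "perpendicular")
  expect_error(compute_r_trace(p$par, other), "alignment")
  expect_error(magic_from_pair(p$par, other), "alignment")
})
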
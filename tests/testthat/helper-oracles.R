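# Independent oracles used across the suite. These deliberately avoid
# the package's own computational paths.

# Brute-force numerical convolution of exp(-(t - t0)/tau) (t >= t0)
# with a Gaussian of width sigma, by adaptive quadrature per time point.
numeric_exgauss <- function(t, tau, sigma, t0 = 0) {
  vapply(t, function(ti) {
    stats::integrate(
      function(s) stats::dnorm(s, mean = t0, sd = sigma) *
        exp(-pmax(ti - s, 0) / tau) * (ti - s >= 0),
      lower = t0 - 8 * sigma, upper = max(t0 + 8 * sigma, ti),
      rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
}

# Closed-form fraction of a truncated single exponential (start at 0,
# acquisition stops at t_max) emitted after t_cut.
exp_fraction_after <- function(tau, t_cut = 1, t_max = 10.5) {
  (exp(-t_cut / tau) - exp(-t_max / tau)) / (1 - exp(-t_max / tau))
}

# Mean arrival time of an exponential truncated at t_max.
truncated_exp_mean <- function(tau, t_max = 10.5) {
  tau - t_max * exp(-t_max / tau) / (1 - exp(-t_max / tau))
}

# 1-D grid search for the best mono-exponential tail description of a
# decay: for each candidate tau, amplitude and background follow by
# weighted linear least squares; returns the tau minimizing the
# weighted residual sum of squares.
grid_search_tau <- function(t, y, taus = seq(0.5, 4, by = 1e-3)) {
  w <- 1 / pmax(y, 1)
  best_tau <- NA_real_
  best_rss <- Inf
  for (tau in taus) {
    x <- exp(-(t - t[1]) / tau)
    X <- cbind(x, 1)
    fit <- stats::lm.wfit(X, y, w)
    rss <- sum(w * fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_tau <- tau
    }
  }
  best_tau
}

# Small fixtures shared across tests.
fixture_model <- function(tau = 2.6, background = 0) {
  decay_model(data.frame(amplitude = 1, lifetime = tau),
              background_rate = background)
}
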
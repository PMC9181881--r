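#' Estimate the constant background of a decay
#'
#' Mean counts per bin over the pre-rise region, i.e. all bins lying
#' entirely before -0.5 ns. With the default grid starting at -1 ns
#' this region holds 20 bins of pure background.
#'
#' @param decay a [decay_curve()].
#' @return Estimated background, counts per bin.
#' @export
estimate_background <- function(decay) {
  stopifnot(inherits(decay, "decay_curve"))
  edges <- bin_edges(decay$grid)
  pre <- which(edges[-1] <= -0.5)
  if (length(pre) == 0)
    stop("insufficient baseline: grid has no bins before -0.5 ns")
  mean(decay$counts[pre])
}

#' Peak-normalize a background-subtracted decay
#'
#' Subtracts the estimated (or supplied) background and divides by the
#' maximum, so the peak is exactly 1.
#'
#' @param decay a [decay_curve()].
#' @param background counts per bin; default [estimate_background()].
#' @return Numeric vector, peak value exactly 1.
#' @export
normalize_decay <- function(decay, background = NULL) {
  stopifnot(inherits(decay, "decay_curve"))
  if (is.null(background)) background <- estimate_background(decay)
  x <- decay$counts - background
  m <- max(x)
  if (m <= 0) stop("degenerate signal: decay is all background")
  x / m
}

#' Fraction of photons emitted after a cut time
#'
#' Background-subtracted photon sum over [t_cut, t_hi] divided by the
#' sum over the full window. Bins are assigned by their centers, so
#' with the default 25 ps grid a cut at 1 ns falls exactly on a bin
#' edge.
#'
#' @param decay a [decay_curve()].
#' @param t_cut ns; must lie inside `total_window`.
#' @param total_window the full integration range (default -1 to
#'   10.5 ns).
#' @param background counts per bin; default [estimate_background()].
#' @return Fraction in [0, 1] (clipped against noise-driven overshoot).
#' @export
fraction_after <- function(decay, t_cut = 1.0,
                           total_window = time_window(-1, 10.5),
                           background = NULL) {
  stopifnot(inherits(decay, "decay_curve"))
  total_window <- as_time_window(total_window)
  if (t_cut <= total_window$t_lo || t_cut >= total_window$t_hi)
    stop("t_cut must lie strictly inside the total window")
  if (is.null(background)) background <- estimate_background(decay)
  x <- decay$counts - background
  total_mask <- window_mask(decay$grid, total_window)
  tail_mask <- window_mask(decay$grid, time_window(t_cut, total_window$t_hi))
  total <- sum(x[total_mask])
  if (total <= 0) stop("degenerate signal: no photons above background")
  min(max(sum(x[tail_mask]) / total, 0), 1)
}

#' Mono-exponential tail fit
#'
#' Weighted least-squares fit of A exp(-t/tau) + b on a late time
#' window (default 1.5-10.5 ns), with Poisson weights 1/max(counts, 1)
#' (Neyman convention). No IRF reconvolution is performed: the window
#' start is far beyond the instrument response width, so these are
#' phenomenological tail lifetimes.
#'
#' @param decay a [decay_curve()].
#' @param window fit window, default `time_window(1.5, 10.5)`.
#' @return An object of class `tail_fit` with fields `tau` (ns),
#'   `amplitude` (counts at the window start), `background`
#'   (counts/bin), `tau_stderr`, `chi2_reduced`, `window`, and the
#'   underlying `fit` object.
#' @examples
#' m <- decay_model(data.frame(amplitude = 1, lifetime = 2.6),
#'                  background_rate = 2)
#' d <- simulate_decay(m, make_irf(80), n_photons = 1e6, seed = 7,
#'                     emission_wavelength = 305)
#' tail_fit(d)$tau
#' @export
tail_fit <- function(decay, window = time_window(1.5, 10.5)) {
  stopifnot(inherits(decay, "decay_curve"))
  window <- as_time_window(window)
  mask <- window_mask(decay$grid, window)
  if (sum(mask) < 20) stop("fewer than 20 bins in the fit window")
  t <- bin_centers(decay$grid)[mask]
  y <- as.numeric(decay$counts[mask])
  bg0 <- estimate_background(decay)
  if (sum(y) - bg0 * length(y) <= 0)
    stop("degenerate signal: no photons above background in the window")
  w <- 1 / pmax(y, 1)

  # initialization: log-linear regression on lightly smoothed,
  # background-subtracted counts
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  pos <- which(ys - bg0 > 0)
  if (length(pos) >= 5) {
    cf <- stats::coef(stats::lm(log(ys[pos] - bg0) ~ t[pos]))
    tau0 <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else 2.5
    a0 <- exp(cf[1] + cf[2] * window$t_lo)
  } else {
    tau0 <- 2.5
    a0 <- max(y[1] - bg0, 1)
  }
  tau0 <- min(max(tau0, 0.2), 20)

  # fit relative to the window start so `amplitude` is counts at t_lo
  ts <- t - window$t_lo
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-ts / tau) + b,
      start = list(A = max(a0, 1e-3), tau = tau0, b = max(bg0, 0)),
      lower = c(A = 0, tau = 1e-3, b = 0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  est <- stats::coef(fit)
  if (est[["tau"]] <= 0) stop("fit failure: non-positive lifetime")
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["tau"]],
                 error = function(e) NA_real_)
  resid <- y - stats::fitted(fit)
  chi2 <- sum(w * resid^2) / (length(y) - 3)
  structure(
    list(tau = unname(est[["tau"]]), amplitude = unname(est[["A"]]),
         background = unname(est[["b"]]), tau_stderr = unname(se),
         chi2_reduced = chi2, window = window, fit = fit),
    class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf(
    "<tail_fit> tau = %.3f +/- %.3f ns on [%g, %g] ns (chi2_red %.2f)\n",
    x$tau, x$tau_stderr, x$window$t_lo, x$window$t_hi, x$chi2_reduced))
  invisible(x)
}
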
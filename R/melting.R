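#' Two-state melting model parameters
#'
#' Phenomenological logistic description of a duplex melting curve at
#' 260 nm: folded fraction f(T) = 1 / (1 + exp((T - tm)/width)),
#' linear folded/melted baselines, and the hyperchromicity (percent
#' absorbance increase at 96 degC relative to 20 degC). The melted
#' baseline intercept is solved so the model hyperchromicity equals
#' the requested value exactly.
#'
#' @param tm melting temperature, degC.
#' @param width logistic transition width, degC (> 0).
#' @param a_folded_ref folded-branch absorbance at 20 degC (> 0).
#' @param hyperchromicity_pct percent increase of A(96) over A(20).
#' @param baseline_slopes length-2 numeric: per-degC slopes of the
#'   folded and melted baselines.
#' @return An object of class `melt_params`.
#' @export
melt_model_params <- function(tm, width, a_folded_ref, hyperchromicity_pct,
                              baseline_slopes = c(0.0004, 0.0004)) {
  if (width <= 0) stop("width must be positive")
  if (a_folded_ref <= 0) stop("a_folded_ref must be positive")
  if (hyperchromicity_pct < 0) stop("hyperchromicity_pct must be non-negative")
  sf <- baseline_slopes[1]; sm <- baseline_slopes[2]
  h <- hyperchromicity_pct / 100
  f20 <- 1 / (1 + exp((20 - tm) / width))
  f96 <- 1 / (1 + exp((96 - tm) / width))
  af <- a_folded_ref
  # melted baseline anchored at 96 degC: Bm(T) = am + sm (T - 96);
  # solve am from A(96) = (1 + h) A(20), linear in am
  lhs <- (1 - f96) - (1 + h) * (1 - f20)
  rhs <- (1 + h) * (af * f20 + sm * (20 - 96) * (1 - f20)) -
    (af + sf * (96 - 20)) * f96
  if (abs(lhs) < 1e-12) stop("degenerate melting model: transition spans the range")
  am <- rhs / lhs
  structure(
    list(tm = tm, width = width, a_folded_ref = a_folded_ref,
         hyperchromicity_pct = hyperchromicity_pct,
         baseline_slopes = c(folded = sf, melted = sm),
         a_melted_96 = am),
    class = "melt_params")
}

# Noise-free model absorbance
melt_model_absorbance <- function(params, temperatures) {
  f <- 1 / (1 + exp((temperatures - params$tm) / params$width))
  bf <- params$a_folded_ref + params$baseline_slopes[["folded"]] *
    (temperatures - 20)
  bm <- params$a_melted_96 + params$baseline_slopes[["melted"]] *
    (temperatures - 96)
  bf * f + bm * (1 - f)
}

#' Melting curve container
#' @param temperatures degC, ascending, at least 8 points.
#' @param absorbance positive absorbance values at 260 nm.
#' @return An object of class `melting_curve` (also a data.frame).
#' @export
melting_curve <- function(temperatures, absorbance) {
  if (length(temperatures) != length(absorbance))
    stop("temperatures and absorbance must have the same length")
  if (length(temperatures) < 8) stop("at least 8 points are required")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be ascending")
  if (any(absorbance <= 0)) stop("absorbance must be positive")
  structure(data.frame(temperature = temperatures, absorbance = absorbance),
            class = c("melting_curve", "data.frame"))
}

#' Simulate a 260 nm melting curve
#'
#' Evaluates the two-state model and adds Gaussian noise;
#' `noise_sd = 0` returns exact model values.
#'
#' @param params a [melt_model_params()].
#' @param temperatures degC, ascending, within [0, 100].
#' @param noise_sd Gaussian noise standard deviation (absorbance
#'   units).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return A [melting_curve()].
#' @export
simulate_melting_curve <- function(params, temperatures = seq(20, 96, by = 1),
                                   noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "melt_params"))
  if (any(temperatures < 0 | temperatures > 100))
    stop("temperatures must lie within [0, 100] degC")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be ascending")
  a <- melt_model_absorbance(params, temperatures)
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sd))
  melting_curve(temperatures, pmax(a, 1e-6))
}

#' Fit a two-state melting model
#'
#' Nonlinear least squares of the logistic two-state model with linear
#' baselines. Initialization is deterministic: Tm from the maximum of
#' a smoothed numerical derivative, baselines from the outer 20% of
#' the temperature range.
#'
#' @param curve a [melting_curve()].
#' @return An object of class `melt_fit`: `tm`, `width`,
#'   `baseline_folded` (intercept at 20 degC, slope),
#'   `baseline_melted` (intercept at 96 degC, slope),
#'   `hyperchromicity_pct` (from the fitted model at 20 and 96 degC),
#'   `rmse`, and the `fit` object.
#' @export
fit_melting <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  temp <- curve$temperature
  a <- curve$absorbance
  if (max(a) - min(a) < 1e-9 * max(a))
    stop("no transition: curve is flat")
  # derivative-based Tm guess
  da <- diff(a) / diff(temp)
  tm_mid <- (temp[-1] + temp[-length(temp)]) / 2
  das <- stats::filter(da, rep(1 / 5, 5), sides = 2)
  das[is.na(das)] <- da[is.na(das)]
  tm0 <- tm_mid[which.max(das)]
  n_edge <- max(3L, ceiling(0.2 * length(temp)))
  lo_idx <- seq_len(n_edge)
  hi_idx <- seq(length(temp) - n_edge + 1, length(temp))
  if (tm0 <= temp[max(lo_idx)] || tm0 >= temp[min(hi_idx)])
    stop("no transition: inflection not interior to the range")
  cf_lo <- stats::coef(stats::lm(a[lo_idx] ~ I(temp[lo_idx] - 20)))
  cf_hi <- stats::coef(stats::lm(a[hi_idx] ~ I(temp[hi_idx] - 96)))
  start <- list(tm = tm0, lw = log(2),
                af = unname(cf_lo[1]), sf = unname(cf_lo[2]),
                am = unname(cf_hi[1]), sm = unname(cf_hi[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ (af + sf * (temp - 20)) / (1 + exp((temp - tm) / exp(lw))) +
        (am + sm * (temp - 96)) *
          (1 - 1 / (1 + exp((temp - tm) / exp(lw)))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  est <- as.list(stats::coef(fit))
  width <- exp(est$lw)
  model_at <- function(T_) {
    f <- 1 / (1 + exp((T_ - est$tm) / width))
    (est$af + est$sf * (T_ - 20)) * f + (est$am + est$sm * (T_ - 96)) * (1 - f)
  }
  a20 <- model_at(20); a96 <- model_at(96)
  structure(
    list(tm = est$tm, width = width,
         baseline_folded = c(intercept = est$af, slope = est$sf),
         baseline_melted = c(intercept = est$am, slope = est$sm),
         hyperchromicity_pct = 100 * (a96 - a20) / a20,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         model_at = model_at, fit = fit),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit> Tm = %.2f degC, width = %.2f degC, hyperchromicity = %.1f%% (rmse %.2g)\n",
    x$tm, x$width, x$hyperchromicity_pct, x$rmse))
  invisible(x)
}

#' Model-free hyperchromicity
#'
#' 100 * (A(t_hot) - A(t_ref)) / A(t_ref) read directly from the data
#' with linear interpolation; temperatures at most 2 degC outside the
#' measured range are clamped to the nearest endpoint.
#'
#' @param curve a [melting_curve()].
#' @param t_ref,t_hot readout temperatures, degC (default 20 and 96).
#' @return Percent increase.
#' @export
hyperchromicity <- function(curve, t_ref = 20, t_hot = 96) {
  stopifnot(inherits(curve, "melting_curve"))
  rng <- range(curve$temperature)
  for (t in c(t_ref, t_hot))
    if (t < rng[1] - 2 || t > rng[2] + 2)
      stop("extrapolation error: readout temperature > 2 degC outside the data")
  readout <- function(t) {
    t <- min(max(t, rng[1]), rng[2])
    stats::approx(curve$temperature, curve$absorbance, xout = t)$y
  }
  a_ref <- readout(t_ref)
  100 * (readout(t_hot) - a_ref) / a_ref
}

#' Melting temperature of a fitted model
#'
#' Returns the fitted Tm; with `check_derivative = TRUE` it is
#' cross-checked against the argmax of dA/dT of the fitted model on a
#' dense grid (agreement within width/100 for flat-baseline models).
#'
#' @param fit a [fit_melting()] result.
#' @param check_derivative logical.
#' @return Tm in degC.
#' @export
melting_temperature <- function(fit, check_derivative = FALSE) {
  stopifnot(inherits(fit, "melt_fit"))
  if (check_derivative) {
    tt <- seq(fit$tm - 5 * fit$width, fit$tm + 5 * fit$width, length.out = 4001)
    aa <- fit$model_at(tt)
    t_star <- tt[which.max(abs(diff(aa)))]
    if (abs(t_star - fit$tm) > max(fit$width, 1))
      warning("derivative maximum far from fitted tm; sloped baselines?")
  }
  fit$tm
}
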
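#' Steady-state emission spectrum
#'
#' @param wavelengths nm, strictly ascending.
#' @param intensities non-negative, same length; maximum must be > 0.
#' @return An object of class `ss_spectrum`.
#' @export
steady_state_spectrum <- function(wavelengths, intensities) {
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have the same length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly ascending")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (max(intensities) <= 0) stop("spectrum must have positive maximum")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities)),
            class = "ss_spectrum")
}

#' @export
print.ss_spectrum <- function(x, ...) {
  cat(sprintf("<ss_spectrum> %d points, %g-%g nm, peak near %g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$wavelengths[which.max(x$intensities)]))
  invisible(x)
}

#' Detector spectral response curve
#'
#' Strictly positive wavelength-dependent sensitivity of the detection
#' chain; measured spectra are the true spectra multiplied by it, and
#' [correct_response()] divides it back out.
#'
#' @param wavelengths nm, strictly ascending.
#' @param sensitivity strictly positive values, same length.
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(wavelengths, sensitivity) {
  if (length(wavelengths) != length(sensitivity))
    stop("wavelengths and sensitivity must have the same length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly ascending")
  if (any(sensitivity <= 0))
    stop("invalid response: sensitivity must be strictly positive")
  structure(list(wavelengths = as.numeric(wavelengths),
                 sensitivity = as.numeric(sensitivity)),
            class = "response_curve")
}

#' Default detection-chain response
#'
#' A smooth monochromator + microchannel-plate style sensitivity,
#' highest in the UV and falling towards the red.
#'
#' @param wavelengths nm.
#' @return A [response_curve()].
#' @export
default_response_curve <- function(wavelengths = seq(290, 460, by = 1)) {
  s <- 0.55 + 0.45 * exp(-((wavelengths - 310) / 160)^2)
  response_curve(wavelengths, s)
}

# --- band shapes in wavenumber space -----------------------------------

nm_to_wavenumber <- function(lambda_nm) 1e7 / lambda_nm

# Log-normal (Siano-Metzler) band profile in wavenumber; asym = 0 is the
# Gaussian limit. fwhm is the width parameter; the realized full width
# at half maximum is fwhm * sinh(asym)/asym (= fwhm when asym = 0).
lognormal_band <- function(nu, center, fwhm, asym = 0) {
  if (abs(asym) < 1e-8)
    return(exp(-4 * log(2) * ((nu - center) / fwhm)^2))
  arg <- 1 + 2 * asym * (nu - center) / fwhm
  out <- numeric(length(nu))
  ok <- arg > 0
  out[ok] <- exp(-log(2) * (log(arg[ok]) / asym)^2)
  out
}

band_fwhm_realized <- function(fwhm, asym) {
  if (abs(asym) < 1e-8) fwhm else fwhm * sinh(asym) / asym
}

# Evaluate a multi-band spectrum (list of bands with center_nm,
# fwhm_cm1, height, asym) at wavelengths in nm.
eval_band_spectrum <- function(bands, wavelengths) {
  nu <- nm_to_wavenumber(wavelengths)
  s <- numeric(length(wavelengths))
  for (b in bands) {
    s <- s + b$height * lognormal_band(
      nu, nm_to_wavenumber(b$center_nm), b$fwhm_cm1,
      if (is.null(b$asym)) 0 else b$asym)
  }
  s
}

# Numerical FWHM (cm^-1) of a continuous band-sum spectrum, found by
# root solving on each side of the maximum on the wavenumber axis.
band_spectrum_fwhm <- function(bands, nu_range = c(20000, 36000)) {
  f <- function(nu) {
    s <- numeric(length(nu))
    for (b in bands) {
      s <- s + b$height * lognormal_band(
        nu, nm_to_wavenumber(b$center_nm), b$fwhm_cm1,
        if (is.null(b$asym)) 0 else b$asym)
    }
    s
  }
  nu_grid <- seq(nu_range[1], nu_range[2], by = 5)
  vals <- f(nu_grid)
  i_max <- which.max(vals)
  half <- vals[i_max] / 2
  g <- function(nu) f(nu) - half
  lo <- stats::uniroot(g, c(nu_range[1], nu_grid[i_max]), tol = 1e-6)$root
  hi <- stats::uniroot(g, c(nu_grid[i_max], nu_range[2]), tol = 1e-6)$root
  hi - lo
}

#' Simulate a steady-state emission spectrum from a preset
#'
#' Evaluates the preset's calibrated band model (sum of log-normal
#' bands in wavenumber space) on the requested wavelength grid and
#' normalizes the peak to 1. The preset calibration fixes the spectral
#' full width at half maximum and the I(305 nm)/I(420 nm) intensity
#' ratio.
#'
#' @param preset a [get_preset()] object.
#' @param wavelengths nm grid; must contain 305 and 420 nm.
#' @return A [steady_state_spectrum()], peak-normalized.
#' @export
simulate_steady_state_spectrum <- function(preset,
                                           wavelengths = seq(290, 460, by = 1)) {
  stopifnot(inherits(preset, "duplex_preset"))
  if (min(wavelengths) > 305 || max(wavelengths) < 420)
    stop("coverage error: wavelength grid must contain both 305 and 420 nm")
  s <- eval_band_spectrum(preset$spectrum_params$bands, wavelengths)
  steady_state_spectrum(wavelengths, s / max(s))
}
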
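#' Relative importance R of long-lived high-energy emission
#'
#' Quantifies how much the nanosecond-lived fluorescence at 305 nm
#' outweighs that at 420 nm: the ratio of the after-cut photon
#' fractions of the two decays multiplied by the steady-state
#' intensity ratio at the same wavelengths,
#' R = (frac305 / frac420) * (Iss305 / Iss420).
#'
#' @param frac_305 fraction of 305 nm photons emitted after the cut.
#' @param frac_420 fraction of 420 nm photons emitted after the cut
#'   (> 0).
#' @param ss_ratio steady-state intensity ratio I(305)/I(420) (> 0).
#' @param t_cut cut time echoed into the result, ns.
#' @return An object of class `rstat`: list with `r_value`,
#'   `frac_305`, `frac_420`, `ss_ratio_305_420`, `t_cut`.
#' @examples
#' compute_R(0.275, 0.28, 3.9)$r_value
#' @export
compute_R <- function(frac_305, frac_420, ss_ratio, t_cut = 1.0) {
  if (frac_420 <= 0)
    stop("division error: frac_420 must be positive (no long-lived 420 nm signal)")
  if (ss_ratio <= 0) stop("ss_ratio must be positive")
  structure(
    list(r_value = (frac_305 / frac_420) * ss_ratio,
         frac_305 = frac_305, frac_420 = frac_420,
         ss_ratio_305_420 = ss_ratio, t_cut = t_cut),
    class = "rstat")
}

#' @export
print.rstat <- function(x, ...) {
  cat(sprintf(
    "<rstat> R = %.2f  (frac305 = %.3f, frac420 = %.3f, Iss305/Iss420 = %.2f, t_cut = %g ns)\n",
    x$r_value, x$frac_305, x$frac_420, x$ss_ratio_305_420, x$t_cut))
  invisible(x)
}

#' Steady-state intensity ratio between two wavelengths
#'
#' Linearly interpolated I(wl_num)/I(wl_den) on a steady-state
#' spectrum (normally the response-corrected one).
#'
#' @param spectrum an `ss_spectrum`.
#' @param wl_num,wl_den wavelengths, nm; must lie inside the spectrum
#'   range.
#' @return Positive ratio.
#' @export
ss_intensity_ratio <- function(spectrum, wl_num = 305, wl_den = 420) {
  stopifnot(inherits(spectrum, "ss_spectrum"))
  rng <- range(spectrum$wavelengths)
  if (wl_num < rng[1] || wl_num > rng[2] || wl_den < rng[1] || wl_den > rng[2])
    stop("range error: wavelength outside the spectrum")
  i_num <- stats::approx(spectrum$wavelengths, spectrum$intensities,
                         xout = wl_num)$y
  i_den <- stats::approx(spectrum$wavelengths, spectrum$intensities,
                         xout = wl_den)$y
  if (i_den <= 0) stop("division error: zero intensity at the denominator wavelength")
  i_num / i_den
}

#' R statistic from a decay dataset and a steady-state spectrum
#'
#' Chains [fraction_after()] at 305 and 420 nm with
#' [ss_intensity_ratio()] through [compute_R()].
#'
#' @param decays named list of [decay_curve()]s including 305 and
#'   420 nm entries (names are wavelengths in nm).
#' @param spectrum an `ss_spectrum` covering 305-420 nm.
#' @param t_cut cut time, ns (default 1).
#' @param total_window full integration range (default -1 to 10.5 ns).
#' @return An `rstat` object.
#' @export
r_from_dataset <- function(decays, spectrum, t_cut = 1.0,
                           total_window = time_window(-1, 10.5)) {
  wl <- vapply(decays, function(d) d$emission_wavelength, numeric(1))
  if (any(!is.finite(wl)) && !is.null(names(decays)))
    wl <- as.numeric(names(decays))
  i305 <- which(abs(wl - 305) < 1e-6)
  i420 <- which(abs(wl - 420) < 1e-6)
  if (length(i305) != 1 || length(i420) != 1)
    stop("missing input: decays must include 305 and 420 nm")
  f305 <- fraction_after(decays[[i305]], t_cut, total_window)
  f420 <- fraction_after(decays[[i420]], t_cut, total_window)
  compute_R(f305, f420, ss_intensity_ratio(spectrum), t_cut = t_cut)
}
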
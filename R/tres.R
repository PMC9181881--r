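#' Integrate a wavelength series of decays over a time window
#'
#' Per-wavelength background-subtracted photon sums over the window:
#' the raw (uncorrected) emission spectrum of the photons arriving in
#' that window.
#'
#' @param decays named list of [decay_curve()]s; names (or the curves'
#'   `emission_wavelength` fields) give the wavelengths in nm. All
#'   curves must share one grid.
#' @param window a [time_window()].
#' @return Data frame with columns `wavelength` and `intensity`.
#' @export
integrate_window <- function(decays, window) {
  window <- as_time_window(window)
  wl <- decay_wavelengths(decays)
  grid <- decays[[1]]$grid
  for (d in decays)
    if (!same_grid(d$grid, grid)) stop("alignment error: decays on different grids")
  edges <- bin_edges(grid)
  if (window$t_lo < edges[1] - 1e-9 || window$t_hi > edges[length(edges)] + 1e-9)
    stop("range error: window outside the time grid")
  mask <- window_mask(grid, window)
  intensity <- vapply(decays, function(d) {
    bg <- estimate_background(d)
    sum(d$counts[mask] - bg)
  }, numeric(1))
  ord <- order(wl)
  data.frame(wavelength = wl[ord], intensity = unname(intensity[ord]))
}

decay_wavelengths <- function(decays) {
  if (length(decays) < 3) stop("at least 3 wavelengths are required")
  wl <- vapply(decays, function(d) d$emission_wavelength, numeric(1))
  if (any(!is.finite(wl))) {
    if (is.null(names(decays))) stop("decays need emission wavelengths")
    wl <- as.numeric(names(decays))
  }
  if (any(!is.finite(wl))) stop("decays need emission wavelengths")
  if (anyDuplicated(wl)) stop("duplicate emission wavelengths")
  wl
}

#' Correct a spectrum for the detection-chain response
#'
#' Divides intensities by the (linearly interpolated) sensitivity of
#' the detection system, wavelength by wavelength.
#'
#' @param spectrum data.frame with `wavelength` and `intensity`
#'   columns, or an `ss_spectrum`.
#' @param response a [response_curve()] covering the spectrum range.
#' @return Same shape as the input with corrected intensities.
#' @export
correct_response <- function(spectrum, response) {
  stopifnot(inherits(response, "response_curve"))
  if (inherits(spectrum, "ss_spectrum")) {
    s <- correct_response(
      data.frame(wavelength = spectrum$wavelengths,
                 intensity = spectrum$intensities), response)
    return(steady_state_spectrum(s$wavelength, s$intensity))
  }
  wl <- spectrum$wavelength
  if (min(wl) < min(response$wavelengths) - 1e-9 ||
      max(wl) > max(response$wavelengths) + 1e-9)
    stop("invalid response: curve does not cover the spectrum range")
  sens <- stats::approx(response$wavelengths, response$sensitivity,
                        xout = wl)$y
  if (any(!is.finite(sens)) || any(sens <= 0))
    stop("invalid response: non-positive sensitivity on the spectrum range")
  out <- spectrum
  out$intensity <- spectrum$intensity / sens
  out
}

#' Build time-resolved emission spectra (TRES)
#'
#' For each time window: integrate the per-wavelength decays, correct
#' for the detection response, and peak-normalize. The raw
#' (unnormalized, corrected) spectra are retained alongside.
#'
#' @param decays named list of [decay_curve()]s (see
#'   [integrate_window()]).
#' @param windows list of [time_window()]s.
#' @param response a [response_curve()]; NULL for no correction.
#' @return An object of class `tres`: list with `windows`, `spectra`
#'   (long data.frame: window_lo_ns, window_hi_ns, wavelength,
#'   intensity, normalized_intensity).
#' @export
build_tres <- function(decays, windows, response = NULL) {
  windows <- lapply(windows, as_time_window)
  rows <- lapply(windows, function(w) {
    sp <- integrate_window(decays, w)
    if (!is.null(response)) sp <- correct_response(sp, response)
    peak <- max(sp$intensity)
    norm <- if (peak > 0) sp$intensity / peak else sp$intensity
    data.frame(window_lo_ns = w$t_lo, window_hi_ns = w$t_hi,
               wavelength = sp$wavelength, intensity = sp$intensity,
               normalized_intensity = norm)
  })
  structure(list(windows = windows, spectra = do.call(rbind, rows)),
            class = "tres")
}

#' @export
print.tres <- function(x, ...) {
  cat(sprintf("<tres> %d windows x %d wavelengths\n", length(x$windows),
              length(unique(x$spectra$wavelength))))
  invisible(x)
}

#' Photon budget across time intervals
#'
#' Percentage of all background-subtracted photons (summed over every
#' probed wavelength) that falls into each interval of a disjoint
#' partition of the acquisition range. Percentages sum to 100.
#'
#' @param decays named list of [decay_curve()]s.
#' @param intervals list of [time_window()]s; must be disjoint (edges
#'   may touch) and jointly cover the grid range.
#' @return An object of class `photon_budget`: data.frame with
#'   `t_lo`, `t_hi`, `percentage`.
#' @export
photon_budget <- function(decays, intervals = default_budget_intervals()) {
  intervals <- lapply(intervals, as_time_window)
  lo <- vapply(intervals, function(w) w$t_lo, numeric(1))
  hi <- vapply(intervals, function(w) w$t_hi, numeric(1))
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]; intervals <- intervals[ord]
  if (any(hi[-length(hi)] > lo[-1] + 1e-9))
    stop("partition error: intervals overlap")
  grid <- decays[[1]]$grid
  if (abs(lo[1] - grid$start) > 1e-9 || abs(hi[length(hi)] - grid$stop) > 1e-9 ||
      any(abs(hi[-length(hi)] - lo[-1]) > 1e-9))
    stop("partition error: intervals must exactly cover the full range")
  sums <- vapply(intervals, function(w) sum(integrate_window(decays, w)$intensity),
                 numeric(1))
  total <- sum(sums)
  if (total <= 0) stop("degenerate signal: no photons above background")
  structure(data.frame(t_lo = lo, t_hi = hi, percentage = 100 * sums / total),
            class = c("photon_budget", "data.frame"))
}

#' Default photon-budget partition
#'
#' Three successive intervals with boundaries at 0.1 and 1 ns,
#' spanning the default -1 to 10.5 ns range.
#' @param grid a [time_grid()].
#' @return List of [time_window()]s.
#' @export
default_budget_intervals <- function(grid = time_grid()) {
  list(time_window(grid$start, 0.1), time_window(0.1, 1),
       time_window(1, grid$stop))
}

#' Spectral full width at half maximum on the wavenumber axis
#'
#' Converts the spectrum to wavenumber (1e7 / lambda_nm), locates the
#' two half-maximum crossings by linear interpolation and returns
#' their distance in cm^-1. The spectrum must be unimodal above half
#' maximum.
#'
#' @param spectrum an `ss_spectrum` or data.frame with
#'   `wavelength`/`intensity`.
#' @return Width in cm^-1.
#' @export
spectral_fwhm_wavenumber <- function(spectrum) {
  if (inherits(spectrum, "ss_spectrum")) {
    wl <- spectrum$wavelengths; y <- spectrum$intensities
  } else {
    wl <- spectrum$wavelength; y <- spectrum$intensity
  }
  nu <- nm_to_wavenumber(wl)
  ord <- order(nu)
  nu <- nu[ord]; y <- y[ord]
  half <- max(y) / 2
  above <- y > half
  runs <- rle(above)
  if (sum(runs$values) != 1)
    stop("multimodal error: spectrum crosses half maximum more than twice")
  idx <- which(above)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  if (i1 == 1 || i2 == length(y))
    stop("half-maximum crossing outside the sampled range")
  cross <- function(ia, ib) {
    nu[ia] + (half - y[ia]) * (nu[ib] - nu[ia]) / (y[ib] - y[ia])
  }
  lo <- cross(i1 - 1, i1)
  hi <- cross(i2 + 1, i2)
  abs(hi - lo)
}

#' Peak wavelength with parabolic interpolation
#'
#' Wavelength of the spectrum maximum refined by a parabola through
#' the three samples around the argmax; spectra probed at 5 nm steps
#' thus resolve sub-step peak shifts. A maximum on the grid boundary
#' is returned as-is with an edge flag.
#'
#' @param spectrum an `ss_spectrum` or data.frame with
#'   `wavelength`/`intensity`.
#' @return List with `wavelength` (nm) and `edge` (logical: TRUE when
#'   the maximum sits on the boundary and could not be interpolated).
#' @export
peak_wavelength <- function(spectrum) {
  if (inherits(spectrum, "ss_spectrum")) {
    wl <- spectrum$wavelengths; y <- spectrum$intensities
  } else {
    wl <- spectrum$wavelength; y <- spectrum$intensity
  }
  if (length(wl) == 0) stop("empty spectrum")
  i <- which.max(y)  # ties: smallest wavelength (first index)
  if (i == 1 || i == length(y))
    return(list(wavelength = wl[i], edge = TRUE))
  y3 <- y[(i - 1):(i + 1)]
  x3 <- wl[(i - 1):(i + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (abs(denom) < .Machine$double.eps * max(abs(y3), 1))
    return(list(wavelength = x3[2], edge = FALSE))
  # vertex of the parabola through three (assumed equidistant) points
  h <- (x3[3] - x3[1]) / 2
  delta <- 0.5 * (y3[1] - y3[3]) / denom
  list(wavelength = x3[2] + delta * h, edge = FALSE)
}
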
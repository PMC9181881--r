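# Named duplex presets: ground truth for one system x excitation x
# buffer condition. Raw targets (photon fractions per time window,
# tail lifetimes, spectral widths, anisotropy plateaus, melting
# parameters) live in inst/extdata/presets/presets.json; the
# multi-exponential amplitudes realizing them are solved here by a
# deterministic calibration at load time.

preset_cache <- new.env(parent = emptyenv())

load_preset_config <- function() {
  if (!is.null(preset_cache$config)) return(preset_cache$config)
  path <- system.file("extdata", "presets", "presets.json", package = "tcspcdna")
  if (path == "") stop("preset configuration not found; is the package installed?")
  preset_cache$config <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset_cache$config
}

# --- spectrum calibration ----------------------------------------------
# Two-band model: main emission band at the steady-state peak plus a
# weak visible (excimer-like) band. The main band width and visible
# band height are solved so the realized spectral FWHM (wavenumber)
# and the I(305)/I(420) ratio hit their targets; alternation of two
# monotone 1-D root solves converges to high accuracy.
calibrate_spectrum_bands <- function(sp) {
  point_ratio <- function(bands)
    eval_band_spectrum(bands, 305) / eval_band_spectrum(bands, 420)
  make_bands <- function(width, height) list(
    list(center_nm = sp$peak_nm, fwhm_cm1 = width, height = 1, asym = 0),
    list(center_nm = sp$vis_center_nm, fwhm_cm1 = sp$vis_fwhm_cm1,
         height = height, asym = 0))
  width <- sp$fwhm_cm1
  height <- 0.1
  for (iter in 1:6) {
    height <- stats::uniroot(
      function(h) point_ratio(make_bands(width, h)) - sp$ratio_305_420,
      c(1e-6, 2), tol = 1e-10)$root
    width <- stats::uniroot(
      function(w) band_spectrum_fwhm(make_bands(w, height)) - sp$fwhm_cm1,
      c(2000, sp$fwhm_cm1 + 1000), tol = 1e-8)$root
  }
  make_bands(width, height)
}

# --- decay-model calibration -------------------------------------------
# Three kinetic pools with fixed lifetimes: prompt (10/30 ps, the
# IRF-unresolvable femto/picosecond emission collapsed into one
# effective pool), intermediate (100/300 ps) and the long tail
# (lifetime from the tail-fit targets). Pool weights are solved
# exactly from the target photon fractions in the three canonical
# windows [-1,0.1]/[0.1,1]/[1,10.5] ns, with window integrals computed
# through the package's own forward model so leakage between windows
# is accounted for.
pool_components <- function(tau_long) {
  list(
    prompt = data.frame(amplitude = c(2 / 3 / 0.010, 1 / 3 / 0.030),
                        lifetime = c(0.010, 0.030)),
    mid = data.frame(amplitude = c(0.5 / 0.1, 0.5 / 0.3),
                     lifetime = c(0.1, 0.3)),
    long = data.frame(amplitude = 1 / tau_long, lifetime = tau_long))
}

calibrate_decay_model <- function(targets, tau_long, irf, background_rate = 0) {
  stopifnot(length(targets) == 3, abs(sum(targets) - 1) < 1e-9)
  grid <- irf$grid
  pools <- pool_components(tau_long)
  masks <- list(window_mask(grid, time_window(grid$start, 0.1)),
                window_mask(grid, time_window(0.1, 1)),
                window_mask(grid, time_window(1, grid$stop)))
  W <- matrix(0, 3, 3)
  for (k in seq_along(pools)) {
    mu <- expected_signal(pools[[k]], irf, grid)
    tot <- sum(mu)
    for (j in 1:3) W[j, k] <- sum(mu[masks[[j]]]) / tot
  }
  x <- solve(W, targets)
  if (any(x < -1e-9))
    stop("infeasible calibration targets: negative pool weight")
  x <- pmax(x, 0)
  comps <- do.call(rbind, lapply(seq_along(pools), function(k) {
    cc <- pools[[k]]
    cc$amplitude <- cc$amplitude * x[k]
    cc
  }))
  comps <- comps[comps$amplitude > 0, , drop = FALSE]
  decay_model(comps, background_rate = background_rate)
}

# --- long/intermediate emission band shapes (spectral-mode presets) ----
# The 1-10 ns product spectrum P(lambda) = S(lambda) * f(lambda) is
# itself modeled as a broad UV band peaking below 305 nm plus a weak
# visible band; the visible height and the UV band center are solved
# so P(305)/P(420) equals the target R statistic and the visible/UV
# photon ratio of the [1,10] ns TRES equals its target.
calibrate_long_band <- function(cfg, wavelengths) {
  uv_mask <- wavelengths >= 305 & wavelengths <= 400
  vis_mask <- wavelengths >= 410 & wavelengths <= 440
  make_bands <- function(uv_center, vis_height) list(
    list(center_nm = uv_center, fwhm_cm1 = cfg$long_uv_fwhm_cm1,
         height = 1, asym = 0),
    list(center_nm = cfg$long_vis_center_nm, fwhm_cm1 = cfg$long_vis_fwhm_cm1,
         height = vis_height, asym = 0))
  ratio_305_420 <- function(bands)
    eval_band_spectrum(bands, 305) / eval_band_spectrum(bands, 420)
  vu <- function(bands) {
    p <- eval_band_spectrum(bands, wavelengths)
    sum(p[vis_mask]) / sum(p[uv_mask])
  }
  uv_center <- 299
  vis_height <- 0.15
  for (iter in 1:8) {
    vis_height <- stats::uniroot(
      function(h) ratio_305_420(make_bands(uv_center, h)) - cfg$R_target,
      c(1e-5, 5), tol = 1e-10)$root
    uv_center <- stats::uniroot(
      function(cc) vu(make_bands(cc, vis_height)) - cfg$vu_ratio,
      c(270, 304), tol = 1e-8)$root
  }
  make_bands(uv_center, vis_height)
}

mid_band <- function(cfg) list(
  list(center_nm = cfg$mid_center_nm, fwhm_cm1 = cfg$mid_fwhm_cm1,
       height = 1, asym = 0),
  list(center_nm = cfg$mid_vis_center_nm, fwhm_cm1 = cfg$mid_vis_fwhm_cm1,
       height = cfg$mid_vis_height, asym = 0))

# Per-wavelength window-fraction targets for a spectral-mode preset.
spectral_targets <- function(cfg, bands_ss, wavelengths, response) {
  s <- eval_band_spectrum(bands_ss, wavelengths)
  s <- s / max(s)
  resp <- stats::approx(response$wavelengths, response$sensitivity,
                        xout = wavelengths)$y
  weight <- s * resp
  p <- eval_band_spectrum(calibrate_long_band(cfg, wavelengths), wavelengths)
  m <- eval_band_spectrum(mid_band(cfg), wavelengths)
  # budget closure: intensity-weighted mean of the after-1-ns (and
  # mid-window) fractions over all probed wavelengths equals the
  # preset's photon-budget targets
  c_long <- cfg$budget_after1 * sum(weight) / sum(resp * p)
  c_mid <- cfg$budget_mid * sum(weight) / sum(resp * m)
  f <- c_long * p / s
  g1 <- c_mid * m / s
  if (any(f + g1 >= 0.98))
    stop("infeasible spectral calibration: prompt fraction would be negative")
  data.frame(wavelength = wavelengths, g0 = 1 - f - g1, g1 = g1, f = f,
             weight = weight / max(weight))
}

anchor_targets <- function(cfg, bands_ss, response) {
  wl <- cfg$wavelengths
  s <- eval_band_spectrum(bands_ss, wl)
  s <- s / max(eval_band_spectrum(bands_ss, seq(300, 460, by = 1)))
  resp <- stats::approx(response$wavelengths, response$sensitivity, xout = wl)$y
  weight <- s * resp
  data.frame(wavelength = wl, g0 = 1 - cfg$f_after1 - cfg$g_mid,
             g1 = cfg$g_mid, f = cfg$f_after1,
             weight = weight / max(weight))
}

#' Retrieve a calibrated duplex preset
#'
#' Returns the ground-truth generator for one duplex system,
#' excitation wavelength and buffer condition. Decay models per
#' emission wavelength are calibrated deterministically so that
#' noise-free analysis reproduces the preset's encoded photon
#' fractions, tail lifetimes, anisotropy plateaus, steady-state
#' intensity ratio, spectral width and hyperchromicity.
#'
#' Available combinations: pApT with excitation 267 or 285 nm in
#' standard, diluted_6x or KCl_matched buffer; A20T20 with excitation
#' 285 nm in standard buffer.
#'
#' @param system "pApT" (polymeric, ~1000 bp) or "A20T20" (20 bp
#'   oligomer).
#' @param excitation excitation wavelength, 267 or 285 nm.
#' @param buffer "standard", "diluted_6x" or "KCl_matched".
#' @return An object of class `duplex_preset`: grid, IRF width,
#'   `decay_models` (named by emission wavelength, nm),
#'   `anisotropy_models` (305 and 420 nm), calibrated
#'   `spectrum_params`, `ss_ratio_305_420`, `melt_params`,
#'   `quantum_yield` (metadata), `wavelengths`, `targets`
#'   (per-wavelength window fractions and relative photon weights) and
#'   `response` (detection-chain response curve).
#' @examples
#' p <- get_preset("pApT", 267, "standard")
#' p$decay_models[["305"]]
#' @export
get_preset <- function(system = c("pApT", "A20T20"),
                       excitation = c(267, 285),
                       buffer = c("standard", "diluted_6x", "KCl_matched")) {
  system <- match.arg(as.character(system), c("pApT", "A20T20"))
  buffer <- match.arg(buffer)
  excitation <- as.numeric(excitation)[1]
  key <- paste(system, excitation, buffer, sep = ".")
  cfgs <- load_preset_config()
  if (!key %in% names(cfgs$presets))
    stop("unknown preset: ", key)
  if (!is.null(preset_cache[[key]])) return(preset_cache[[key]])

  cfg <- cfgs$presets[[key]]
  # buffer aliases share another preset's decay models
  if (!is.null(cfg$alias_decays)) {
    parts <- strsplit(cfg$alias_decays, ".", fixed = TRUE)[[1]]
    base <- get_preset(parts[1], as.numeric(parts[2]), parts[3])
    out <- base
    out$buffer <- buffer
    out$melt_params <- preset_melt_params(cfgs, system, buffer)
    preset_cache[[key]] <- out
    return(out)
  }
  fraction_scale <- 1
  if (!is.null(cfg$base)) {
    base_cfg <- cfgs$presets[[cfg$base]]
    fraction_scale <- cfg$fraction_scale
    cfg <- utils::modifyList(base_cfg, cfg[setdiff(names(cfg), c("base"))])
  }

  grid <- time_grid(cfgs$grid$start, cfgs$grid$stop, cfgs$grid$bin_width)
  irf <- make_irf(cfgs$irf_fwhm_ps, grid, t0 = 0)
  response <- default_response_curve()
  sys_cfg <- cfgs$systems[[system]]
  bands_ss <- calibrate_spectrum_bands(sys_cfg$spectrum)

  if (identical(cfg$mode, "spectral")) {
    wavelengths <- seq(cfg$wavelength_start, cfg$wavelength_stop,
                       by = cfg$wavelength_step)
    targets <- spectral_targets(cfg, bands_ss, wavelengths, response)
    tau_long <- stats::approx(cfg$tau_long_anchor_nm, cfg$tau_long_anchor_ns,
                              xout = wavelengths, rule = 2)$y
  } else {
    wavelengths <- cfg$wavelengths
    targets <- anchor_targets(cfg, bands_ss, response)
    tau_long <- cfg$tau_long
  }
  if (fraction_scale != 1) {
    targets$f <- targets$f * fraction_scale
    targets$g0 <- 1 - targets$f - targets$g1
    if (any(targets$g0 <= 0)) stop("infeasible fraction scaling")
  }

  decay_models <- stats::setNames(lapply(seq_along(wavelengths), function(i) {
    calibrate_decay_model(
      unlist(targets[i, c("g0", "g1", "f")]), tau_long[i], irf,
      background_rate = cfg$background_rate)
  }), as.character(wavelengths))
  targets$tau_long <- tau_long

  aniso_cfg <- cfgs$anisotropy[[system]]
  anisotropy_models <- stats::setNames(lapply(names(aniso_cfg), function(wl) {
    ac <- aniso_cfg[[wl]]
    comps <- as.data.frame(ac$components)
    aniso_model(r0 = ac$r_inf + sum(comps$amplitude),
                decay_components = comps, r_inf = ac$r_inf)
  }), names(aniso_cfg))

  out <- structure(
    list(system = system, excitation = excitation, buffer = buffer,
         grid = grid, irf_fwhm_ps = cfgs$irf_fwhm_ps,
         wavelengths = wavelengths,
         decay_models = decay_models,
         anisotropy_models = anisotropy_models,
         spectrum_params = list(bands = bands_ss),
         ss_ratio_305_420 = sys_cfg$spectrum$ratio_305_420,
         melt_params = preset_melt_params(cfgs, system, buffer),
         quantum_yield = sys_cfg$quantum_yield,
         targets = targets, response = response),
    class = "duplex_preset")
  preset_cache[[key]] <- out
  out
}

preset_melt_params <- function(cfgs, system, buffer) {
  mk <- paste(system, buffer, sep = ".")
  mc <- cfgs$melting[[mk]]
  if (is.null(mc)) stop("no melting parameters for ", mk)
  melt_model_params(mc$tm, mc$width, mc$a_folded_ref, mc$hyperchromicity_pct,
                    mc$baseline_slopes)
}

#' @export
print.duplex_preset <- function(x, ...) {
  cat(sprintf(
    "<duplex_preset> %s, excitation %g nm, %s buffer; %d emission wavelengths\n",
    x$system, x$excitation, x$buffer, length(x$wavelengths)))
  invisible(x)
}

#' Preset instrument response
#' @param preset a [get_preset()] object.
#' @return The preset's Gaussian [make_irf()].
#' @export
preset_irf <- function(preset) {
  stopifnot(inherits(preset, "duplex_preset"))
  make_irf(preset$irf_fwhm_ps, preset$grid, t0 = 0)
}

#' Simulate a full magic-angle decay dataset from a preset
#'
#' One decay per preset emission wavelength. The per-wavelength photon
#' number is `n_photons` scaled by the relative measured intensity
#' (true spectrum times detection response, normalized to 1 at its
#' maximum), emulating equal acquisition times across wavelengths.
#'
#' @param preset a [get_preset()] object.
#' @param n_photons expected signal photons at the strongest
#'   wavelength.
#' @param seed integer; per-wavelength sub-seeds are derived from it.
#' @param wavelengths subset of preset wavelengths (default all).
#' @return Named list of [decay_curve()]s keyed by wavelength.
#' @export
simulate_preset_decays <- function(preset, n_photons = 1e6, seed = 1,
                                   wavelengths = preset$wavelengths) {
  stopifnot(inherits(preset, "duplex_preset"))
  irf <- preset_irf(preset)
  idx <- match(wavelengths, preset$wavelengths)
  if (any(is.na(idx))) stop("wavelength not in preset")
  out <- stats::setNames(lapply(seq_along(idx), function(k) {
    i <- idx[k]
    n_i <- max(round(n_photons * preset$targets$weight[i]), 100)
    # the encoded background is a count *rate*: per-bin counts at the
    # nominal 1e6-photon acquisition, scaled with acquisition length
    m <- preset$decay_models[[i]]
    m$background_rate <- m$background_rate * n_i / 1e6
    simulate_decay(
      m, irf, n_photons = n_i,
      seed = derive_seed(seed, 10L + i),
      emission_wavelength = preset$wavelengths[i],
      excitation_wavelength = preset$excitation,
      polarization = "magic", system = preset$system)
  }), as.character(wavelengths))
  out
}

#' Simulate a polarized pair from a preset
#'
#' @param preset a [get_preset()] object.
#' @param wavelength emission wavelength with an anisotropy model
#'   (305 or 420 nm).
#' @param n_photons expected signal photons of the underlying
#'   population decay.
#' @param seed integer seed.
#' @return List with `parallel` and `perpendicular` [decay_curve()]s.
#' @export
simulate_preset_pair <- function(preset, wavelength = 305, n_photons = 1e6,
                                 seed = 1) {
  stopifnot(inherits(preset, "duplex_preset"))
  wl <- as.character(wavelength)
  if (!wl %in% names(preset$anisotropy_models))
    stop("no anisotropy model at ", wavelength, " nm")
  if (!wl %in% names(preset$decay_models))
    stop("no decay model at ", wavelength, " nm")
  m <- preset$decay_models[[wl]]
  # per-channel background at this acquisition length (each channel
  # collects roughly half the photons of a nominal 1e6-photon run)
  m$background_rate <- m$background_rate * n_photons / 2e6
  simulate_polarized_pair(
    m, preset$anisotropy_models[[wl]],
    preset_irf(preset), n_photons = n_photons, seed = seed,
    emission_wavelength = wavelength,
    excitation_wavelength = preset$excitation, system = preset$system)
}
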
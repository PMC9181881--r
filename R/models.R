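#' Multi-exponential decay model
#'
#' The molecular fluorescence response is modeled as a sum of
#' exponentials, I(t) = sum_i a_i exp(-t / tau_i) for t >= 0, plus a
#' constant dark-count background expectation per bin. Entire duplex
#' decays need several time constants; the presets use five.
#'
#' @param components two-column matrix or data.frame with columns
#'   `amplitude` (non-negative) and `lifetime` (ns, strictly positive),
#'   one row per exponential component.
#' @param background_rate expected background counts per bin (>= 0).
#' @return An object of class `decay_model`.
#' @examples
#' m <- decay_model(data.frame(amplitude = 1, lifetime = 2.6))
#' @export
decay_model <- function(components, background_rate = 0) {
  components <- as.data.frame(components)
  if (!all(c("amplitude", "lifetime") %in% names(components)))
    stop("components must have columns 'amplitude' and 'lifetime'")
  if (nrow(components) < 1L) stop("at least one component is required")
  if (any(components$lifetime <= 0)) stop("lifetimes must be strictly positive")
  if (any(components$amplitude < 0)) stop("amplitudes must be non-negative")
  if (all(components$amplitude == 0)) stop("amplitudes must not all be zero")
  if (background_rate < 0) stop("background_rate must be non-negative")
  structure(
    list(components = components[c("amplitude", "lifetime")],
         background_rate = background_rate),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> %d components, background %.3g counts/bin\n",
              nrow(x$components), x$background_rate))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Time-dependent anisotropy model
#'
#' r(t) = r_inf + sum_j b_j exp(-t / theta_j). Physically admissible
#' anisotropies lie in [-0.2, 0.4]: 0.4 for parallel absorption and
#' emission dipoles, -0.2 for perpendicular ones.
#'
#' @param r0 initial anisotropy r(0); must equal
#'   `r_inf + sum(amplitude)` within 1e-6 (it is stored for clarity).
#' @param decay_components data.frame with columns `amplitude` (may be
#'   negative) and `correlation_time` (ns, positive); may have zero rows
#'   for a constant anisotropy.
#' @param r_inf plateau anisotropy at long times, in [-0.2, 0.4].
#' @return An object of class `aniso_model`.
#' @export
aniso_model <- function(r0, decay_components = NULL, r_inf = r0) {
  if (is.null(decay_components))
    decay_components <- data.frame(amplitude = numeric(0),
                                   correlation_time = numeric(0))
  decay_components <- as.data.frame(decay_components)
  if (nrow(decay_components) > 0) {
    if (!all(c("amplitude", "correlation_time") %in% names(decay_components)))
      stop("decay_components must have columns 'amplitude' and 'correlation_time'")
    if (any(decay_components$correlation_time <= 0))
      stop("correlation times must be strictly positive")
  }
  if (r_inf < -0.2 || r_inf > 0.4) stop("r_inf outside [-0.2, 0.4]")
  implied_r0 <- r_inf + sum(decay_components$amplitude)
  if (abs(r0 - implied_r0) > 1e-6)
    stop("r0 must equal r_inf + sum of component amplitudes")
  structure(
    list(r0 = r0,
         decay_components = decay_components[
           , c("amplitude", "correlation_time"), drop = FALSE],
         r_inf = r_inf),
    class = "aniso_model"
  )
}

#' Evaluate an anisotropy model
#' @param model an [aniso_model()].
#' @param t times, ns (r(t) for t < 0 is evaluated with the same
#'   formula; the model is only meaningful after time zero).
#' @return Numeric vector r(t).
#' @export
eval_anisotropy <- function(model, t) {
  stopifnot(inherits(model, "aniso_model"))
  r <- rep(model$r_inf, length(t))
  dc <- model$decay_components
  for (j in seq_len(nrow(dc)))
    r <- r + dc$amplitude[j] * exp(-pmax(t, 0) / dc$correlation_time[j])
  r
}

check_anisotropy_range <- function(model, grid) {
  t <- bin_centers(grid)
  r <- eval_anisotropy(model, t[t >= 0])
  if (any(r < -0.2 - 1e-9 | r > 0.4 + 1e-9))
    stop("invalid anisotropy model: r(t) leaves [-0.2, 0.4] on the grid")
  invisible(TRUE)
}
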
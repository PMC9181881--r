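# Tabular readers/writers. Decays travel as TSV with '#key value'
# header comments; spectra, melting curves and anisotropy traces as
# two-to-four-column CSV; fit results as JSON records. All times are
# ns, wavelengths nm, temperatures degC.

#' Write a decay histogram to TSV
#'
#' Header comment lines (#system, #excitation_nm, #emission_nm,
#' #polarization, #seed) followed by tab-separated `time_ns` (bin
#' centers) and `counts` columns.
#'
#' @param decay a [decay_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "decay_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#system\t", decay$system),
    paste0("#excitation_nm\t", decay$excitation_wavelength),
    paste0("#emission_nm\t", decay$emission_wavelength),
    paste0("#polarization\t", decay$polarization),
    paste0("#seed\t", decay$seed),
    "time_ns\tcounts"), con)
  utils::write.table(
    data.frame(time_ns = sprintf("%.6f", bin_centers(decay$grid)),
               counts = decay$counts),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a decay histogram from TSV
#'
#' Inverse of [write_decay()]: validates integer non-negative counts
#' and a uniform time grid; errors carry the offending line number.
#'
#' @param path TSV file written by [write_decay()].
#' @return A [decay_curve()].
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- strsplit(sub("^#", "", lines[hdr_idx]), "\t")
  meta <- stats::setNames(
    vapply(hdr, function(x) if (length(x) > 1) x[2] else NA_character_,
           character(1)),
    vapply(hdr, `[`, character(1), 1))
  body_start <- if (length(hdr_idx)) max(hdr_idx) + 1 else 1
  if (!grepl("^time_ns\tcounts", lines[body_start]))
    stop(sprintf("parse error at line %d: expected 'time_ns\\tcounts' header",
                 body_start))
  data_lines <- lines[(body_start + 1):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected two tab-separated fields",
                 body_start + bad[1]))
  t <- as.numeric(vapply(parts, `[`, character(1), 1))
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  bad <- which(!is.finite(t) | !is.finite(counts))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-numeric value",
                 body_start + bad[1]))
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-9)
  if (length(bad))
    stop(sprintf("parse error at line %d: counts must be non-negative integers",
                 body_start + bad[1]))
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop(sprintf("non-uniform grid at line %d",
                 body_start + which(abs(dt - dt[1]) > 1e-6)[1] + 1))
  grid <- time_grid(t[1] - dt[1] / 2, t[length(t)] + dt[1] / 2, dt[1])
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  decay_curve(grid, counts,
              emission_wavelength = num_or_na(meta[["emission_nm"]]),
              excitation_wavelength = num_or_na(meta[["excitation_nm"]]),
              polarization = if (meta[["polarization"]] %in%
                                 c("magic", "parallel", "perpendicular"))
                meta[["polarization"]] else "magic",
              system = meta[["system"]],
              seed = suppressWarnings(as.integer(meta[["seed"]])))
}

#' Write/read a two-column spectrum CSV
#' @param spectrum an `ss_spectrum` or data.frame with
#'   wavelength/intensity columns.
#' @param path file path.
#' @return `path` / an `ss_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  if (inherits(spectrum, "ss_spectrum"))
    spectrum <- data.frame(wavelength_nm = spectrum$wavelengths,
                           intensity = spectrum$intensities)
  utils::write.csv(spectrum, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  steady_state_spectrum(df[[1]], df[[2]])
}

#' Write/read a melting curve CSV (temperature_C, absorbance_260)
#' @param curve a [melting_curve()].
#' @param path file path.
#' @return `path` / a [melting_curve()].
#' @export
write_melting_curve <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  utils::write.csv(
    data.frame(temperature_C = curve$temperature,
               absorbance_260 = curve$absorbance),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_melting_curve
#' @export
read_melting_curve <- function(path) {
  df <- utils::read.csv(path)
  melting_curve(df[[1]], df[[2]])
}

#' Write an anisotropy trace CSV
#'
#' Columns: time_ns, r, r_stderr, defined_flag.
#' @param trace an [compute_r_trace()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_r_trace <- function(trace, path) {
  stopifnot(inherits(trace, "aniso_trace"))
  utils::write.csv(
    data.frame(time_ns = bin_centers(trace$grid),
               r = trace$r_values, r_stderr = trace$r_stderr,
               defined_flag = as.integer(trace$defined)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes all scalar fields of a `tail_fit`, `melt_fit` or `rstat`
#' object as a JSON record.
#' @param x the fit/statistic object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  keep <- Filter(function(v) is.numeric(v) || is.character(v),
                 unclass(x)[!names(unclass(x)) %in% c("fit", "model_at")])
  keep$class <- class(x)[1]
  if (inherits(x, "tail_fit"))
    keep$window <- c(x$window$t_lo, x$window$t_hi)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
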
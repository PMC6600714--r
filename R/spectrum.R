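# Spectrum objects: wavelength-sampled nonnegative functions (cross-sections
# or lineshapes). All overlap quantities downstream integrate these with one
# declared quadrature rule (trapezoid on the stored grid).

SPECTRUM_KINDS <- c("cross_section", "lineshape", "extinction")

#' Construct a spectrum
#'
#' A spectrum is a nonnegative function sampled on a strictly increasing
#' wavelength grid. It is the currency of every overlap computation in the
#' package: nanostructure absorption/scattering cross-sections, dye emission
#' and absorption lineshapes, and extinction curves are all spectra.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths in
#'   nanometres, length at least 2.
#' @param value Nonnegative finite numeric vector, same length.
#' @param kind One of `"cross_section"` (nm^2), `"lineshape"`
#'   (dimensionless, typically area-normalized) or `"extinction"`.
#' @return An object of class `mef_spectrum`.
#' @export
spectrum <- function(wavelength_nm, value, kind = "lineshape") {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L)
    stop("spectrum needs at least 2 wavelength samples", call. = FALSE)
  if (length(value) != length(wavelength_nm))
    stop("wavelength and value vectors must have equal length", call. = FALSE)
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("spectrum values must be finite and nonnegative", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind),
            class = "mef_spectrum")
}

#' @export
print.mef_spectrum <- function(x, ...) {
  cat(sprintf("<mef_spectrum> kind=%s, %d points, %.1f-%.1f nm, peak %.4g at %.1f nm\n",
              x$kind, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), max(x$value),
              x$wavelength_nm[which.max(x$value)]))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "mef_spectrum")

# Trapezoid rule on an arbitrary grid -- the single quadrature rule used for
# every integral over a stored spectrum.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Integrated area of a spectrum (trapezoid rule)
#' @param s A `mef_spectrum`.
#' @return Scalar area in value-units times nm.
#' @export
spectrum_area <- function(s) {
  stopifnot(is_spectrum(s))
  trapz(s$wavelength_nm, s$value)
}

# Resample a spectrum onto an arbitrary grid: linear interpolation inside the
# stored support, zero outside. Deterministic and order-independent.
resample_spectrum_values <- function(s, grid_nm) {
  stats::approx(s$wavelength_nm, s$value, xout = grid_nm,
                method = "linear", yleft = 0, yright = 0)$y
}

# Union grid of two spectra (sorted, deduplicated).
union_grid <- function(s1, s2) {
  sort(unique(c(s1$wavelength_nm, s2$wavelength_nm)))
}

#' Parametric dye lineshape
#'
#' Generates a unit-area emission or absorption lineshape on a wavelength
#' grid. `"gaussian"` is Gaussian in wavelength; `"lognormal"` is Gaussian in
#' log-wavelength with its mode at `peak_nm` (the mild red-tail asymmetry
#' typical of measured dye spectra). The curve is normalized to unit area
#' under the trapezoid rule on `grid_nm`.
#'
#' @param peak_nm Peak wavelength; must lie inside the grid.
#' @param fwhm_nm Full width at half maximum, nm (> 0).
#' @param shape `"gaussian"` or `"lognormal"`.
#' @param grid_nm Strictly increasing wavelength grid.
#' @param cutoff_fwhm Truncate the lineshape to exactly zero beyond this many
#'   FWHM from the peak (default `Inf`, no truncation). Used by the synthetic
#'   system generator to make genuinely disjoint spectra representable on a
#'   finite grid.
#' @return A `mef_spectrum` of kind `"lineshape"` with unit trapezoid area
#'   and maximum at the grid point nearest `peak_nm`.
#' @export
dye_lineshape <- function(peak_nm, fwhm_nm, shape = c("gaussian", "lognormal"),
                          grid_nm, cutoff_fwhm = Inf) {
  shape <- match.arg(shape)
  if (fwhm_nm <= 0) stop("fwhm_nm must be positive", call. = FALSE)
  if (peak_nm < min(grid_nm) || peak_nm > max(grid_nm))
    stop("peak_nm lies outside the wavelength grid", call. = FALSE)
  if (shape == "gaussian") {
    v <- exp(-4 * log(2) * ((grid_nm - peak_nm) / fwhm_nm)^2)
  } else {
    # Gaussian in log-wavelength, mode exactly at peak_nm; sigma chosen so the
    # half-maximum points are fwhm_nm apart: fwhm = 2*peak*sinh(sigma*sqrt(2ln2))
    sigma <- asinh(fwhm_nm / (2 * peak_nm)) / sqrt(2 * log(2))
    v <- exp(-(log(grid_nm / peak_nm))^2 / (2 * sigma^2))
  }
  if (is.finite(cutoff_fwhm))
    v[abs(grid_nm - peak_nm) > cutoff_fwhm * fwhm_nm] <- 0
  area <- trapz(grid_nm, v)
  spectrum(grid_nm, v / area, kind = "lineshape")
}

#' Spectral overlap ratio
#'
#' Bounded measure of how much of the dye emission band is covered by the
#' nanostructure absorption band. Both spectra are resampled to their union
#' grid (linear interpolation, zero outside support) and peak-normalized;
#' the ratio is the area under the pointwise minimum divided by the area
#' under the normalized emission:
#' \deqn{\mathrm{ratio} = \int \min(\hat A, \hat E)\, d\lambda \big/ \int \hat E \, d\lambda}
#' The result lies in \[0, 1\]: 1 for identical shapes, 0 for disjoint bands.
#' Conjugates at or above the 40% threshold are treated as metal-enhancement
#' dominated; below it, quenching dominated.
#'
#' @param ns_absorption Nanostructure absorption cross-section spectrum.
#' @param dye_emission Dye emission lineshape spectrum (not identically zero).
#' @return Scalar overlap fraction in \[0, 1\].
#' @export
overlap_ratio <- function(ns_absorption, dye_emission) {
  stopifnot(is_spectrum(ns_absorption), is_spectrum(dye_emission))
  grid <- union_grid(ns_absorption, dye_emission)
  a <- resample_spectrum_values(ns_absorption, grid)
  e <- resample_spectrum_values(dye_emission, grid)
  if (max(e) <= 0)
    stop("dye emission is identically zero on the common grid", call. = FALSE)
  if (max(a) <= 0) return(0)
  a <- a / max(a)
  e <- e / max(e)
  trapz(grid, pmin(a, e)) / trapz(grid, e)
}

#' Spectral overlap integral Jfp
#'
#' Overlap integral between the nanostructure absorption cross-section and
#' the area-normalized dye emission lineshape, with the usual Forster
#' lambda^4 weighting, normalized by the total nanostructure absorption and
#' the solution context (particle concentration and cuvette path):
#' \deqn{J_{fp} = \frac{\int \sigma_{abs}(\lambda)\,\hat E(\lambda)\,\lambda^4\, d\lambda}
#'   {\int \sigma_{abs}(\lambda)\, d\lambda \cdot C_{NR} \cdot l}}
#' with wavelength in nm, `C_NR` in molar and `l` in cm, so Jfp carries
#' M^-1 cm^-1 nm^4 scale. Feeds the quenching rate.
#'
#' @param ns_absorption Nanostructure absorption cross-section spectrum.
#' @param dye_emission Dye emission spectrum; area-normalized internally, so
#'   the result is invariant to its overall scale.
#' @param C_NR_molar Nanostructure concentration in mol/L (default 1 nM).
#' @param l_cm Cuvette path length in cm (default 1).
#' @return Nonnegative scalar Jfp; 0 for disjoint spectra.
#' @export
overlap_integral_jfp <- function(ns_absorption, dye_emission,
                                 C_NR_molar = 1e-9, l_cm = 1) {
  stopifnot(is_spectrum(ns_absorption), is_spectrum(dye_emission))
  if (C_NR_molar <= 0 || l_cm <= 0)
    stop("C_NR_molar and l_cm must be positive", call. = FALSE)
  grid <- union_grid(ns_absorption, dye_emission)
  a <- resample_spectrum_values(ns_absorption, grid)
  e <- resample_spectrum_values(dye_emission, grid)
  denom_sigma <- trapz(grid, a)
  if (denom_sigma <= 0)
    stop("nanostructure absorption is identically zero; Jfp undefined",
         call. = FALSE)
  e_area <- trapz(grid, e)
  if (e_area <= 0)
    stop("dye emission is identically zero on the common grid", call. = FALSE)
  e <- e / e_area
  trapz(grid, a * e * grid^4) / (denom_sigma * C_NR_molar * l_cm)
}

#' Read / write spectrum CSV files
#'
#' Plain two-column CSV with header `wavelength_nm,value` and an optional
#' leading `# kind=<kind>` comment line. Parse errors name the offending
#' file line.
#'
#' @param path File path.
#' @return `read_spectrum_csv` returns a `mef_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kind <- "lineshape"
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    m <- regmatches(lines[i], regexec("#\\s*kind=([a-z_]+)", lines[i]))[[1]]
    if (length(m) == 2L) kind <- m[2]
    i <- i + 1L
  }
  if (i > length(lines) || !grepl("^\\s*wavelength_nm\\s*,\\s*value\\s*$", lines[i]))
    stop("line ", i, ": expected header 'wavelength_nm,value'", call. = FALSE)
  data_lines <- seq.int(i + 1L, length.out = max(0L, length(lines) - i))
  w <- numeric(0); v <- numeric(0)
  for (ln in data_lines) {
    txt <- trimws(lines[ln])
    if (txt == "") next
    parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", ln, ": expected two comma-separated fields, got '",
           txt, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(parts))
    if (any(is.na(num)))
      stop("line ", ln, ": non-numeric field in '", txt, "'", call. = FALSE)
    if (num[2] < 0)
      stop("line ", ln, ": negative spectrum value ", num[2], call. = FALSE)
    if (length(w) > 0L && num[1] <= w[length(w)])
      stop("line ", ln, ": wavelengths must be strictly increasing",
           call. = FALSE)
    w <- c(w, num[1]); v <- c(v, num[2])
  }
  if (length(w) < 2L)
    stop("spectrum file has fewer than 2 data rows: ", path, call. = FALSE)
  spectrum(w, v, kind = kind)
}

#' @rdname read_spectrum_csv
#' @param s A `mef_spectrum` to write.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", s$kind), con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.17g,%.17g", s$wavelength_nm, s$value), con)
  invisible(path)
}
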
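# Bundled preset catalog and the synthetic-system generator. Everything is
# constructible offline and deterministically: nanostructure spectra are
# generated analytically at load time, dye lineshapes are parametric.

#' Path of the bundled preset catalog
#' @return File path of the packaged `presets.json`.
#' @export
preset_catalog_path <- function() {
  system.file("extdata", "presets.json", package = "mefopt", mustWork = TRUE)
}

read_preset_catalog <- function(catalog = preset_catalog_path()) {
  jsonlite::read_json(catalog, simplifyVector = TRUE)
}

#' Names of the bundled presets
#' @param catalog Path to a preset catalog JSON (default: bundled).
#' @return List with character vectors `dyes` and `nanostructures`.
#' @export
preset_names <- function(catalog = preset_catalog_path()) {
  cat_data <- read_preset_catalog(catalog)
  list(dyes = names(cat_data$dyes),
       nanostructures = names(cat_data$nanostructures))
}

build_preset_dye <- function(name, spec, grid_nm) {
  dye_model(name = name, Q0 = spec$Q0, tau0_ns = spec$tau0_ns,
            emission = dye_lineshape(spec$emission$peak_nm,
                                     spec$emission$fwhm_nm,
                                     spec$emission$shape, grid_nm),
            absorption = dye_lineshape(spec$absorption$peak_nm,
                                       spec$absorption$fwhm_nm,
                                       spec$absorption$shape, grid_nm))
}

build_preset_ns <- function(name, spec, grid_nm) {
  nanostructure_model(name = name, material = spec$material,
                      h_nm = spec$h_nm, R_nm = spec$R_nm, grid_nm = grid_nm)
}

#' Load a dye / nanostructure preset pair
#'
#' The catalog bundles three dyes (fluorescein, rhodamine_green,
#' rhodamine_red) and five nanostructures (GNP_r10, SNP_r10, GNR_40x20,
#' SNR_40x20, GNR_60x25: gold/silver spheres of 10 nm radius and
#' 40 nm x 20 nm / 60 nm x 25 nm rods). Dye parameters are representative
#' literature-style values stored in one editable JSON file; nanostructure
#' spectra are generated analytically at load time. Deterministic, no RNG.
#'
#' @param dye_name Dye preset name.
#' @param ns_name Nanostructure preset name.
#' @param catalog Path to a catalog JSON (default: bundled catalog; point
#'   this at your own file to extend the inventory).
#' @return List with elements `dye` (a `mef_dye`) and `ns`
#'   (a `mef_nanostructure`).
#' @export
load_preset <- function(dye_name, ns_name, catalog = preset_catalog_path()) {
  cat_data <- read_preset_catalog(catalog)
  if (!dye_name %in% names(cat_data$dyes))
    stop("unknown dye preset '", dye_name, "'; available: ",
         paste(names(cat_data$dyes), collapse = ", "), call. = FALSE)
  if (!ns_name %in% names(cat_data$nanostructures))
    stop("unknown nanostructure preset '", ns_name, "'; available: ",
         paste(names(cat_data$nanostructures), collapse = ", "),
         call. = FALSE)
  g <- cat_data$grid_nm
  grid_nm <- seq(g$from, g$to, by = g$by)
  list(dye = build_preset_dye(dye_name, cat_data$dyes[[dye_name]], grid_nm),
       ns = build_preset_ns(ns_name, cat_data$nanostructures[[ns_name]],
                            grid_nm))
}

#' Generate a synthetic dye / nanostructure system with a target overlap
#'
#' Builds a Gaussian dye emission and a Gaussian-peaked synthetic
#' nanostructure absorption whose computed [overlap_ratio()] matches
#' `overlap_target` within 0.02, by root-finding on the peak separation
#' (the overlap is continuous and strictly decreasing in the separation).
#' The lineshapes are truncated at 3.5 FWHM so a zero target yields
#' genuinely disjoint spectra. Used in tests to force either lifetime
#' branch deterministically; the nanostructure's synthetic absorption
#' stands in for a computed cross-section and is labelled as such.
#'
#' @param seed Integer seed; jitters the shared peak position and width so
#'   different seeds give different, reproducible systems.
#' @param overlap_target Target overlap fraction in \[0, 1\].
#' @return List with `dye`, `ns`, and `achieved_overlap`.
#' @export
synthetic_system <- function(seed, overlap_target) {
  if (overlap_target < 0 || overlap_target > 1)
    stop("overlap_target must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  grid_nm <- seq(300, 1400, by = 0.5)
  em_peak <- 650 + stats::runif(1, -10, 10)
  fwhm <- 40 + stats::runif(1, 0, 10)
  emission <- dye_lineshape(em_peak, fwhm, "gaussian", grid_nm,
                            cutoff_fwhm = 3.5)
  make_ns <- function(delta) {
    # red-shift the synthetic plasmon band away from the emission
    shape <- dye_lineshape(em_peak + delta, fwhm, "gaussian", grid_nm,
                           cutoff_fwhm = 3.5)
    # synthetic absorption cross-section: scaled lineshape, nm^2 scale
    spectrum(grid_nm, shape$value * 100, kind = "cross_section")
  }
  delta_max <- 8 * fwhm  # supports disjoint beyond 7 FWHM separation
  delta <- if (overlap_target >= 1) {
    0
  } else if (overlap_target <= 0) {
    delta_max
  } else {
    f <- function(d) overlap_ratio(make_ns(d), emission) - overlap_target
    stats::uniroot(f, c(0, delta_max), tol = 1e-3)$root
  }
  ns_abs <- make_ns(delta)
  achieved <- overlap_ratio(ns_abs, emission)
  if (abs(achieved - overlap_target) > 0.02)
    stop(sprintf("could not reach overlap target %.3f (achieved %.3f)",
                 overlap_target, achieved), call. = FALSE)
  dye <- dye_model("synthetic_dye", Q0 = 0.9, tau0_ns = 4.0,
                   emission = emission, absorption = emission)
  ns <- nanostructure_model("synthetic_ns", material = "Au",
                            h_nm = 40, R_nm = 10,
                            absorption = ns_abs,
                            scattering = spectrum(grid_nm,
                                                  ns_abs$value * 0.1,
                                                  "cross_section"))
  list(dye = dye, ns = ns, achieved_overlap = achieved)
}
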
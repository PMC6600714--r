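# Domain models: dyes, nanostructures, conjugate geometry.

#' Fluorophore model
#'
#' @param name Label.
#' @param Q0 Quantum yield, in (0, 1].
#' @param tau0_ns Natural (unperturbed) fluorescence lifetime, ns (> 0).
#' @param emission,absorption `mef_spectrum` lineshapes; emission must not be
#'   identically zero (it is area-normalized in the overlap integrals).
#' @return An object of class `mef_dye`.
#' @export
dye_model <- function(name, Q0, tau0_ns, emission, absorption) {
  if (!is.numeric(Q0) || Q0 <= 0 || Q0 > 1)
    stop("Q0 must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(tau0_ns) || tau0_ns <= 0)
    stop("tau0_ns must be positive", call. = FALSE)
  stopifnot(is_spectrum(emission), is_spectrum(absorption))
  if (max(emission$value) <= 0)
    stop("emission spectrum is identically zero", call. = FALSE)
  structure(list(name = name, Q0 = Q0, tau0_ns = tau0_ns,
                 emission = emission, absorption = absorption),
            class = "mef_dye")
}

#' @export
print.mef_dye <- function(x, ...) {
  cat(sprintf("<mef_dye> %s: Q0=%.3g, tau0=%.3g ns, emission peak %.0f nm\n",
              x$name, x$Q0, x$tau0_ns,
              x$emission$wavelength_nm[which.max(x$emission$value)]))
  invisible(x)
}

#' Metal nanostructure model
#'
#' An ellipsoidal gold or silver nanostructure with its optical
#' cross-sections and solution context. If `absorption`/`scattering` are not
#' supplied they are generated analytically with
#' [ellipsoid_cross_sections()]; user-supplied spectra (e.g. exported from a
#' boundary-element solver, or measured) take precedence. The permittivity
#' at the plasmon resonance, `eps_res`, is evaluated at the wavelength where
#' the absorption spectrum peaks, by construction keeping the spectral and
#' rate models consistent.
#'
#' @param name Label.
#' @param material `"Au"` or `"Ag"`.
#' @param h_nm Long-axis length, nm.
#' @param R_nm Transverse radius, nm.
#' @param permittivity A `mef_permittivity`; default Drude-Lorentz model for
#'   `material` in water.
#' @param absorption,scattering Optional `mef_spectrum` cross-sections.
#' @param grid_nm Wavelength grid for generated spectra.
#' @param orientation Cross-section orientation treatment passed to
#'   [ellipsoid_cross_sections()]; default `"longitudinal"` for rods
#'   (h > 2R, the longitudinal plasmon mode drives the coupling) and
#'   `"average"` for spheres (identical by symmetry).
#' @param C_NR_molar Particle concentration, mol/L (default 1 nM).
#' @param l_cm Cuvette path length, cm (default 1).
#' @param eps_reference Whether `eps_res` is the metal permittivity relative
#'   to the medium (default) or to vacuum.
#' @return An object of class `mef_nanostructure` with fields including
#'   `eps_res` (complex) and `lambda_res_nm`.
#' @export
nanostructure_model <- function(name, material = c("Au", "Ag"), h_nm, R_nm,
                                permittivity = NULL,
                                absorption = NULL, scattering = NULL,
                                grid_nm = seq(300, 900, by = 1),
                                orientation = NULL,
                                C_NR_molar = 1e-9, l_cm = 1,
                                eps_reference = c("medium", "vacuum")) {
  material <- match.arg(material)
  eps_reference <- match.arg(eps_reference)
  if (h_nm <= 0 || R_nm <= 0) stop("h_nm and R_nm must be positive", call. = FALSE)
  if (C_NR_molar <= 0 || l_cm <= 0)
    stop("C_NR_molar and l_cm must be positive", call. = FALSE)
  if (is.null(permittivity))
    permittivity <- drude_lorentz_permittivity(material)
  if (is.null(orientation))
    orientation <- if (h_nm > 2 * R_nm) "longitudinal" else "average"
  if (is.null(absorption) || is.null(scattering)) {
    cs <- ellipsoid_cross_sections(h_nm, R_nm, permittivity, grid_nm,
                                   orientation = orientation)
    if (is.null(absorption)) absorption <- cs$absorption
    if (is.null(scattering)) scattering <- cs$scattering
  }
  stopifnot(is_spectrum(absorption), is_spectrum(scattering))
  lambda_res <- absorption$wavelength_nm[which.max(absorption$value)]
  eps_raw <- permittivity_eval(permittivity, lambda_res)
  eps_res <- if (eps_reference == "medium") eps_raw / permittivity$n_med^2 else eps_raw
  structure(list(name = name, material = material, h_nm = h_nm, R_nm = R_nm,
                 permittivity = permittivity, absorption = absorption,
                 scattering = scattering, orientation = orientation,
                 lambda_res_nm = lambda_res, eps_res = eps_res,
                 eps_reference = eps_reference,
                 C_NR_molar = C_NR_molar, l_cm = l_cm),
            class = "mef_nanostructure")
}

#' @export
print.mef_nanostructure <- function(x, ...) {
  cat(sprintf("<mef_nanostructure> %s: %s, h=%g nm, R=%g nm, resonance %.0f nm (eps_res=%.2f%+.2fi, vs %s)\n",
              x$name, x$material, x$h_nm, x$R_nm, x$lambda_res_nm,
              Re(x$eps_res), Im(x$eps_res), x$eps_reference))
  invisible(x)
}

#' Conjugate geometry
#'
#' Fluorophore placement relative to the nanostructure: separation distance
#' `r` from the particle surface along the long axis, and the three dipole
#' orientation angles (degrees): `thetaT` between the fluorophore and plasmon
#' dipole moments, `thetaD` between the centre-connecting line and the
#' plasmon dipole, `thetaA` between the centre-connecting line and the
#' fluorophore dipole. Vectorized.
#'
#' @param r_nm Separation distance(s), nm, >= 0.
#' @param thetaT,thetaD,thetaA Angles in degrees, each in \[0, 90\].
#' @return A data.frame of class `mef_geometry`.
#' @export
geometry <- function(r_nm, thetaT, thetaD, thetaA) {
  n <- max(length(r_nm), length(thetaT), length(thetaD), length(thetaA))
  g <- data.frame(r_nm = rep_len(r_nm, n), thetaT = rep_len(thetaT, n),
                  thetaD = rep_len(thetaD, n), thetaA = rep_len(thetaA, n))
  if (any(g$r_nm < 0)) stop("r_nm must be >= 0", call. = FALSE)
  for (a in c("thetaT", "thetaD", "thetaA"))
    if (any(g[[a]] < 0 | g[[a]] > 90))
      stop(a, " must lie in [0, 90] degrees", call. = FALSE)
  class(g) <- c("mef_geometry", "data.frame")
  g
}
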
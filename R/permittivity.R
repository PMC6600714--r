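# Metal permittivity models. The built-in generators are analytic
# Drude/Drude-Lorentz fits for gold and silver; tabulated data can be
# supplied instead. Convention: time dependence exp(-i*omega*t), so a
# passive absorbing metal has Im(eps) >= 0.

SPEED_OF_LIGHT_NM_S <- 2.99792458e17  # nm/s

#' Drude-Lorentz permittivity for gold and silver
#'
#' Analytic complex relative permittivity (relative to vacuum) over the
#' visible / near-IR range. Gold uses a Drude term plus one Lorentz pole
#' capturing the interband transitions (eps_inf = 5.9673,
#' omega_D/2pi = 2113.6 THz, gamma_D/2pi = 15.92 THz, delta_eps = 1.09,
#' Omega_L/2pi = 650.07 THz, Gamma_L/2pi = 104.86 THz); silver uses a Drude
#' term (eps_inf = 3.7, hbar*omega_p = 9.1 eV, hbar*gamma = 0.018 eV).
#' These are standard literature-style fits adequate for quasi-static
#' cross-section modelling, not ellipsometric data.
#'
#' @param material `"Au"` or `"Ag"`.
#' @param n_med Refractive index of the surrounding medium (default 1.33,
#'   aqueous solution).
#' @param support Wavelength range (nm) over which the model is declared
#'   valid; evaluation outside errors.
#' @return An object of class `mef_permittivity`.
#' @export
drude_lorentz_permittivity <- function(material = c("Au", "Ag"), n_med = 1.33,
                                       support = c(250, 1500)) {
  material <- match.arg(material)
  if (n_med <= 0) stop("n_med must be positive", call. = FALSE)
  if (material == "Au") {
    eps_inf <- 5.9673
    wd <- 2 * pi * 2113.6e12; gd <- 2 * pi * 15.92e12
    de <- 1.09
    wl <- 2 * pi * 650.07e12; gl <- 2 * pi * 104.86e12
    fun <- function(lambda_nm) {
      w <- 2 * pi * SPEED_OF_LIGHT_NM_S / lambda_nm
      eps_inf - wd^2 / (w^2 + 1i * gd * w) -
        de * wl^2 / ((w^2 - wl^2) + 1i * gl * w)
    }
  } else {
    eps_inf <- 3.7
    ev <- 1.519267e15  # rad/s per eV
    wp <- 9.1 * ev; g <- 0.018 * ev
    fun <- function(lambda_nm) {
      w <- 2 * pi * SPEED_OF_LIGHT_NM_S / lambda_nm
      eps_inf - wp^2 / (w^2 + 1i * g * w)
    }
  }
  structure(list(material = material, n_med = n_med, support = support,
                 eps_fun = fun, source = "drude_lorentz"),
            class = "mef_permittivity")
}

#' Tabulated permittivity
#'
#' Wraps measured or externally computed optical constants. Linear
#' interpolation between samples; support is the tabulated range.
#'
#' @param wavelength_nm Strictly increasing wavelengths, nm.
#' @param eps_re,eps_im Real and imaginary parts of the relative
#'   permittivity; `eps_im` must be nonnegative everywhere.
#' @param material Label (`"Au"` or `"Ag"`).
#' @param n_med Medium refractive index.
#' @return An object of class `mef_permittivity`.
#' @export
tabulated_permittivity <- function(wavelength_nm, eps_re, eps_im,
                                   material = "Au", n_med = 1.33) {
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(eps_im < 0))
    stop("Im(eps) must be nonnegative (absorbing-metal convention)",
         call. = FALSE)
  fun <- function(lambda_nm) {
    complex(real = stats::approx(wavelength_nm, eps_re, lambda_nm)$y,
            imaginary = stats::approx(wavelength_nm, eps_im, lambda_nm)$y)
  }
  structure(list(material = material, n_med = n_med,
                 support = range(wavelength_nm), eps_fun = fun,
                 source = "tabulated"),
            class = "mef_permittivity")
}

#' Evaluate a permittivity model
#' @param pm A `mef_permittivity`.
#' @param lambda_nm Wavelengths (nm) inside the model's declared support.
#' @return Complex relative permittivity (relative to vacuum).
#' @export
permittivity_eval <- function(pm, lambda_nm) {
  stopifnot(inherits(pm, "mef_permittivity"))
  if (any(lambda_nm < pm$support[1] | lambda_nm > pm$support[2]))
    stop(sprintf("wavelength outside permittivity support [%g, %g] nm",
                 pm$support[1], pm$support[2]), call. = FALSE)
  pm$eps_fun(lambda_nm)
}

#' @export
print.mef_permittivity <- function(x, ...) {
  cat(sprintf("<mef_permittivity> %s (%s), n_med=%.3g, support %g-%g nm\n",
              x$material, x$source, x$n_med, x$support[1], x$support[2]))
  invisible(x)
}
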
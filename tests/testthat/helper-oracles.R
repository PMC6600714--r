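# Independent re-transcriptions of the model equations, used as oracles.
# These are deliberately written as direct one-line translations (using
# cospi instead of cos(deg2rad(.)), integrate() instead of the closed-form
# geometry integral) so they share no code path with the implementation.

oracle_kappa <- function(tT, tD, tA) {
  abs(cospi(tT / 180) - 3 * cospi(tD / 180) * cospi(tA / 180))
}

oracle_qr <- function(Q0, tau0_ns, Jfp, kappa, r_nm) {
  (8.79e-5 * Q0 * Jfp * kappa^2) / (1.344 * (tau0_ns * 1e-9)) * (10 * r_nm)^-6
}

# adaptive quadrature of the original improper integral (double-exponential
# rule on the infinite range)
oracle_I <- function(a, R, h, tol = 1e-12) {
  pracma::quadinf(function(x) 2 / ((x + R^2) * (4 * x + h^2)^1.5),
                  xa = a, xb = Inf, tol = tol)$Q
}

# enhancement-rate transcription; I_fun pluggable so the surrounding complex
# algebra can be checked at machine precision (I_fun = ellipsoid_integral_I)
# or the whole chain checked fully independently (I_fun = oracle_I).
oracle_er <- function(r, thetaD, h, R, eps_res, tau0_ns,
                      I_fun = ellipsoid_integral_I) {
  N <- 1 / ((2 * r + h) * (r * (h + r) + R^2)) - I_fun(r * (h + r), R, h)
  D <- 2 / ((eps_res - 1) * h * R^2) + I_fun(0, R, h)
  Mod(1 + N / D)^2 * cospi(thetaD / 180)^2 / (tau0_ns * 1e-9)
}

oracle_efficiencies <- function(ER, QR) {
  list(TrE = ER / (ER + QR), TrQ = QR / (ER + QR))
}

oracle_tau_mef <- function(ER, TrE, TrQ, tau0_ns) {
  const1 <- (TrE * TrQ^4)^(1 / 3) *
    exp((ER - tau0_ns) / (ER + tau0_ns)) - TrQ / 2
  const1 * tau0_ns + tau0_ns
}

oracle_tau_quench <- function(QR, tau0_ns) {
  1e9 / (QR + 1e9 / tau0_ns)
}

# dense-grid (0.01 nm) evaluation of the min-overlap formula for two
# analytic Gaussian bands
oracle_overlap_gaussians <- function(peak1, fwhm1, peak2, fwhm2,
                                     range_nm, dx = 0.01) {
  grid <- seq(range_nm[1], range_nm[2], by = dx)
  a <- exp(-4 * log(2) * ((grid - peak1) / fwhm1)^2)
  e <- exp(-4 * log(2) * ((grid - peak2) / fwhm2)^2)
  tr <- function(y) sum((y[-1] + y[-length(y)]) * dx) / 2
  tr(pmin(a / max(a), e / max(e))) / tr(e / max(e))
}

# dense-grid evaluation of the overlap-integral formula
oracle_jfp_dense <- function(ns_abs, dye_em, C = 1e-9, l = 1, dx = 0.01) {
  rng <- range(ns_abs$wavelength_nm, dye_em$wavelength_nm)
  grid <- seq(rng[1], rng[2], by = dx)
  a <- stats::approx(ns_abs$wavelength_nm, ns_abs$value, grid,
                     yleft = 0, yright = 0)$y
  e <- stats::approx(dye_em$wavelength_nm, dye_em$value, grid,
                     yleft = 0, yright = 0)$y
  tr <- function(y) sum((y[-1] + y[-length(y)]) * dx) / 2
  e <- e / tr(e)
  tr(a * e * grid^4) / (tr(a) * C * l)
}

# Rayleigh dipole cross-sections of a sphere of radius a_nm
oracle_rayleigh_sphere <- function(a_nm, perm, grid_nm) {
  eps <- permittivity_eval(perm, grid_nm)
  eps_m <- perm$n_med^2
  alpha <- 4 * pi * a_nm^3 * (eps - eps_m) / (eps + 2 * eps_m)
  k <- 2 * pi * perm$n_med / grid_nm
  list(absorption = k * Im(alpha), scattering = k^4 * Mod(alpha)^2 / (6 * pi))
}

# random valid photophysics inputs for the transcription suite
random_photophysics_inputs <- function(n, seed = 101) {
  set.seed(seed)
  h <- runif(n, 20, 80)
  data.frame(
    thetaT = runif(n, 0, 90), thetaD = runif(n, 0, 90),
    thetaA = runif(n, 0, 90),
    r = runif(n, 0.5, 100),
    Q0 = runif(n, 0.1, 1), tau0 = runif(n, 1, 10),
    Jfp = 10^runif(n, 14, 18),
    h = h, R = runif(n, 5, h / 2),
    eps_re = runif(n, -15, -2), eps_im = runif(n, 0, 2),
    overlap = runif(n)
  )
}
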
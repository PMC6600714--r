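# Photophysics of the fluorophore-nanostructure conjugate: orientation
# factor, FRET-type quenching rate, radiative enhancement rate, differential
# enhancement factor, transfer efficiencies, and the two-branch fluorescence
# lifetime. All functions are vectorized over geometry.

MIN_SEPARATION_NM <- 0.1  # guard against the 1/r^6 singularity

deg2rad <- function(x) x * pi / 180

#' Dipole orientation factor kappa
#'
#' \deqn{\kappa = |\cos\theta_T - 3\cos\theta_D\cos\theta_A|}
#' On the \[0, 90\] degree domain kappa lies in \[0, 3\]; it enters the
#' quenching rate as kappa squared.
#'
#' @param thetaT,thetaD,thetaA Angles in degrees, each in \[0, 90\].
#' @return kappa, dimensionless, vectorized.
#' @export
orientation_factor <- function(thetaT, thetaD, thetaA) {
  for (a in list(thetaT, thetaD, thetaA))
    if (any(a < 0 | a > 90))
      stop("orientation angles must lie in [0, 90] degrees", call. = FALSE)
  abs(cos(deg2rad(thetaT)) - 3 * cos(deg2rad(thetaD)) * cos(deg2rad(thetaA)))
}

# scalar core shared by the exported wrapper and the system evaluator
qr_core <- function(Q0, tau0_ns, Jfp, kappa, r_nm) {
  tau0_s <- tau0_ns * 1e-9
  8.79e-5 * Q0 * Jfp * kappa^2 / (1.344 * tau0_s * (10 * r_nm)^6)
}

#' FRET quenching rate
#'
#' Rate of non-radiative energy transfer from the excited fluorophore
#' (donor) into the nanostructure plasmon (acceptor), with the Forster
#' 1/r^6 distance law:
#' \deqn{QR = \frac{8.79\times 10^{-5} \, Q_0 \, J_{fp} \, \kappa^2}
#'   {1.344 \, \tau_0 \, (10\, r[\mathrm{nm}])^6}}
#' The numeric constants follow the standard Forster R0^6 convention (Jfp in
#' M^-1 cm^-1 nm^4, distance in Angstrom, hence the factor 10 on r).
#' `tau0` enters in seconds internally so QR is in Hz.
#'
#' @param dye A `mef_dye` (supplies Q0 and tau0).
#' @param Jfp Overlap integral from [overlap_integral_jfp()].
#' @param kappa Orientation factor from [orientation_factor()].
#' @param r_nm Separation distance, nm (> 0).
#' @return Quenching rate in Hz, vectorized over `kappa`/`r_nm`.
#' @export
quenching_rate <- function(dye, Jfp, kappa, r_nm) {
  stopifnot(inherits(dye, "mef_dye"))
  if (Jfp < 0) stop("Jfp must be nonnegative", call. = FALSE)
  if (any(r_nm <= 0))
    stop("r_nm must be positive (1/r^6 singularity at r = 0)", call. = FALSE)
  qr_core(dye$Q0, dye$tau0_ns, Jfp, kappa, r_nm)
}

#' Ellipsoid image-field integral I(a)
#'
#' The geometry integral of the radiative-enhancement model,
#' \deqn{I(a) = \int_a^\infty \frac{2\, dx}{(x + R^2)(4x + h^2)^{3/2}}}
#' for a prolate spheroid of long-axis `h` and transverse radius `R` (all
#' lengths nm; `x` carries nm^2). Strictly decreasing in `a`, tending to 0.
#'
#' Evaluated in closed form: the substitution s^2 = 4x + h^2 reduces the
#' integrand to 4/(s^2 (s^2 - c)) with c = h^2 - 4 R^2 >= 0, which has a
#' logarithmic antiderivative. Where the log form would lose precision to
#' cancellation (sqrt(c)/s0 small) the equivalent series
#' 4 sum_k c^k / ((2k+3) s0^(2k+3)) is used instead; both agree with
#' adaptive quadrature of the original integrand to better than 1e-8
#' relative.
#'
#' @param a Lower limit, nm^2, >= 0 (vectorized).
#' @param R Transverse radius, nm.
#' @param h Long-axis length, nm.
#' @return I(a), units nm^-3.
#' @export
ellipsoid_integral_I <- function(a, R, h) {
  if (R <= 0 || h <= 0) stop("R and h must be positive", call. = FALSE)
  if (any(a < 0)) stop("a must be >= 0", call. = FALSE)
  cc <- h^2 - 4 * R^2
  s0 <- sqrt(4 * a + h^2)
  out <- numeric(length(s0))
  if (cc == 0) {
    # sphere (h = 2R): integrand is 4/s^4
    return(4 / (3 * s0^3))
  }
  if (cc < 0) {
    # oblate case (h < 2R): arctangent antiderivative
    m <- -cc
    return((4 / m) * (1 / s0 - atan(sqrt(m) / s0) / sqrt(m)))
  }
  t <- sqrt(cc) / s0  # in (0, 1) always since s0 >= h > sqrt(c)
  use_log <- t >= 0.1
  if (any(use_log)) {
    s <- s0[use_log]
    rt <- sqrt(cc)
    out[use_log] <- (4 / cc) * (log((s + rt) / (s - rt)) / (2 * rt) - 1 / s)
  }
  if (any(!use_log)) {
    # series: I = 4 * sum_{k>=0} c^k / ((2k+3) s0^(2k+3)); ratio t^2 < 0.01
    s <- s0[!use_log]
    term <- 1 / (3 * s^3)
    acc <- term
    ck <- rep(1, length(s))
    for (k in 1:12) {
      ck <- ck * cc / s^2
      term_k <- ck / ((2 * k + 3) * s^(3))
      acc <- acc + term_k
      if (max(term_k / acc) < 1e-17) break
    }
    out[!use_log] <- 4 * acc
  }
  out
}

# scalar/vector core of the enhancement rate; D precomputed per system
er_core <- function(r_nm, thetaD, h, R, eps_res, tau0_ns) {
  tau0_s <- tau0_ns * 1e-9
  cos2 <- cos(deg2rad(thetaD))^2
  if (eps_res == 1) return(cos2 / tau0_s)  # no metal contrast: D infinite
  D <- 2 / ((eps_res - 1) * h * R^2) + ellipsoid_integral_I(0, R, h)
  N <- 1 / ((2 * r_nm + h) * (r_nm * (h + r_nm) + R^2)) -
    ellipsoid_integral_I(r_nm * (h + r_nm), R, h)
  Mod(1 + N / D)^2 * cos2 / tau0_s
}

#' Radiative enhancement rate
#'
#' Metal-enhanced radiative rate of a fluorophore near a prolate spheroid,
#' in the quasi-static image-dipole picture:
#' \deqn{ER = \frac{\cos^2\theta_D}{\tau_0}\left|1 + \frac{N(r)}{D}\right|^2}
#' with \eqn{N(r) = \frac{1}{(2r+h)(r(h+r)+R^2)} - I(r(h+r))} and
#' \eqn{D = \frac{2}{(\varepsilon_{res}-1) h R^2} + I(0)}, where
#' \eqn{\varepsilon_{res}} is the (complex) metal permittivity at the
#' longitudinal plasmon resonance. Complex arithmetic throughout; the
#' modulus squared is taken at the end. In the far field (r -> infinity) and
#' in the index-matched limit (eps_res -> 1) ER reduces to the free-space
#' radiative rate cos^2(thetaD)/tau0.
#'
#' @param geom A `mef_geometry` (uses `r_nm` and `thetaD`).
#' @param ns A `mef_nanostructure` (supplies h, R, eps_res).
#' @param dye A `mef_dye` (supplies tau0).
#' @return Enhancement rate in Hz, vectorized over geometry rows.
#' @export
enhancement_rate <- function(geom, ns, dye) {
  stopifnot(inherits(geom, "mef_geometry"), inherits(ns, "mef_nanostructure"),
            inherits(dye, "mef_dye"))
  if (dye$tau0_ns <= 0) stop("tau0 must be positive", call. = FALSE)
  er_core(geom$r_nm, geom$thetaD, ns$h_nm, ns$R_nm, ns$eps_res, dye$tau0_ns)
}

#' Differential enhancement factor
#'
#' \deqn{\Gamma_d = ER - QR} (Hz; may be negative when quenching dominates).
#' Maximizing Gamma_d is the direct design objective.
#'
#' @param ER,QR Enhancement and quenching rates, Hz.
#' @return Gamma_d in Hz.
#' @export
differential_enhancement <- function(ER, QR) {
  if (any(ER < 0) || any(QR < 0))
    stop("rates must be nonnegative", call. = FALSE)
  ER - QR
}

#' Transfer efficiencies
#'
#' Fractional shares of the two plasmon-coupling channels:
#' \eqn{TrE = ER/(ER+QR)}, \eqn{TrQ = QR/(ER+QR)}, so `TrE + TrQ = 1`
#' whenever either rate is nonzero. The fully degenerate case ER = QR = 0
#' returns (0, 0) with `degenerate = TRUE` rather than an error.
#'
#' @param ER,QR Rates in Hz, nonnegative, vectorized.
#' @return List with `TrE`, `TrQ`, `degenerate` (logical).
#' @export
transfer_efficiencies <- function(ER, QR) {
  if (any(ER < 0) || any(QR < 0))
    stop("rates must be nonnegative", call. = FALSE)
  tot <- ER + QR
  degenerate <- tot == 0
  TrE <- ifelse(degenerate, 0, ER / tot)
  TrQ <- ifelse(degenerate, 0, QR / tot)
  list(TrE = TrE, TrQ = TrQ, degenerate = degenerate)
}

#' Two-branch fluorescence lifetime
#'
#' Lifetime of the conjugate, switching on the spectral overlap ratio at a
#' 40% threshold. At or above the threshold metal enhancement dominates
#' (MEF branch):
#' \deqn{\tau = (1 + C_1)\,\tau_0,\quad
#'   C_1 = (TrE\cdot TrQ^4)^{1/3}\exp\!\Big(\frac{ER-\tau_0}{ER+\tau_0}\Big) - \frac{TrQ}{2}}
#' Below the threshold quenching dominates, enhancement is neglected
#' (ER treated as 0, hence TrE = 0) and the lifetime is the reciprocal sum
#' of decay channels:
#' \deqn{\tau = \frac{1}{QR + 1/\tau_0}}
#'
#' The exponent of C1 mixes a rate and a time; by default (`const1_units =
#' "mixed"`) ER enters in Hz and tau0 in ns as plain numbers. The
#' dimensionally consistent alternative `"dimensionless"` uses
#' x = ER*tau0 (SI) and evaluates exp((x-1)/(x+1)).
#'
#' @param ER,QR Rates in Hz.
#' @param TrE,TrQ Transfer efficiencies.
#' @param tau0_ns Natural lifetime, ns.
#' @param overlap Spectral overlap ratio in \[0, 1\].
#' @param threshold Branch threshold (default 0.40).
#' @param const1_units `"mixed"` (default) or `"dimensionless"`, see above.
#' @param tau_floor_ns Positive floor applied with a warning if the MEF
#'   branch expression turns nonpositive (a model pathology, not user error).
#' @return List with `tau_ns` and `branch` (`"mef"` or `"quenching"`).
#' @export
fluorescence_lifetime <- function(ER, QR, TrE, TrQ, tau0_ns, overlap,
                                  threshold = 0.40,
                                  const1_units = c("mixed", "dimensionless"),
                                  tau_floor_ns = 1e-3) {
  const1_units <- match.arg(const1_units)
  if (tau0_ns <= 0) stop("tau0_ns must be positive", call. = FALSE)
  if (overlap < 0 || overlap > 1)
    stop("overlap must lie in [0, 1]", call. = FALSE)
  if (overlap >= threshold) {
    x <- if (const1_units == "mixed") {
      (ER - tau0_ns) / (ER + tau0_ns)
    } else {
      er_tau <- ER * tau0_ns * 1e-9
      (er_tau - 1) / (er_tau + 1)
    }
    const1 <- (TrE * TrQ^4)^(1 / 3) * exp(x) - TrQ / 2
    tau <- (const1 + 1) * tau0_ns
    if (any(tau <= 0)) {
      warning("MEF-branch lifetime nonpositive; clamped to floor of ",
              tau_floor_ns, " ns", call. = FALSE)
      tau <- pmax(tau, tau_floor_ns)
    }
    list(tau_ns = tau, branch = "mef")
  } else {
    # quenching branch: enhancement neglected (ER = 0)
    tau0_s <- tau0_ns * 1e-9
    tau_s <- 1 / (QR + 1 / tau0_s)
    list(tau_ns = tau_s * 1e9, branch = "quenching")
  }
}

#' Precompute a dye-nanostructure system
#'
#' Bundles a dye and a nanostructure together with every quantity that does
#' not depend on geometry: the spectral overlap ratio and branch decision,
#' the overlap integral Jfp, and the resonance permittivity. Evaluating GA
#' specimens against a prebuilt system avoids recomputing the spectral
#' integrals per specimen.
#'
#' @param dye A `mef_dye`.
#' @param ns A `mef_nanostructure`.
#' @param threshold Overlap threshold for the lifetime branch (default 0.40).
#' @param const1_units Passed to [fluorescence_lifetime()].
#' @return An object of class `mef_system`.
#' @export
mef_system <- function(dye, ns, threshold = 0.40,
                       const1_units = c("mixed", "dimensionless")) {
  const1_units <- match.arg(const1_units)
  stopifnot(inherits(dye, "mef_dye"), inherits(ns, "mef_nanostructure"))
  ov <- overlap_ratio(ns$absorption, dye$emission)
  jfp <- overlap_integral_jfp(ns$absorption, dye$emission,
                              ns$C_NR_molar, ns$l_cm)
  structure(list(dye = dye, ns = ns, threshold = threshold,
                 const1_units = const1_units,
                 overlap = ov, Jfp = jfp,
                 branch = if (ov >= threshold) "mef" else "quenching"),
            class = "mef_system")
}

#' @export
print.mef_system <- function(x, ...) {
  cat(sprintf("<mef_system> %s + %s: overlap=%.3f (%s branch), Jfp=%.4g\n",
              x$dye$name, x$ns$name, x$overlap, x$branch, x$Jfp))
  invisible(x)
}

#' Evaluate the full photophysics of one or more geometries
#'
#' Computes, per geometry row, the orientation factor, quenching and
#' enhancement rates, differential enhancement factor, transfer
#' efficiencies, lifetime and branch. This is the evaluation kernel behind
#' the GA cost function and the distance scan.
#'
#' @param system A `mef_system`.
#' @param geom A `mef_geometry` (or anything [geometry()] accepts via its
#'   columns `r_nm`, `thetaT`, `thetaD`, `thetaA`).
#' @return A data.frame with one row per geometry: `r_nm`, `thetaT`,
#'   `thetaD`, `thetaA`, `kappa`, `QR_hz`, `ER_hz`, `gamma_d_hz`, `TrE`,
#'   `TrQ`, `tau_ns`, `branch`, `overlap`, `Jfp`, `degenerate`.
#' @export
evaluate_photophysics <- function(system, geom) {
  stopifnot(inherits(system, "mef_system"))
  if (!inherits(geom, "mef_geometry"))
    geom <- geometry(geom$r_nm, geom$thetaT, geom$thetaD, geom$thetaA)
  if (any(geom$r_nm < MIN_SEPARATION_NM))
    stop("separation distance below the minimum of ", MIN_SEPARATION_NM,
         " nm", call. = FALSE)
  dye <- system$dye; ns <- system$ns
  kappa <- orientation_factor(geom$thetaT, geom$thetaD, geom$thetaA)
  QR <- qr_core(dye$Q0, dye$tau0_ns, system$Jfp, kappa, geom$r_nm)
  ER <- er_core(geom$r_nm, geom$thetaD, ns$h_nm, ns$R_nm, ns$eps_res,
                dye$tau0_ns)
  eff <- transfer_efficiencies(ER, QR)
  lt <- fluorescence_lifetime(ER, QR, eff$TrE, eff$TrQ, dye$tau0_ns,
                              system$overlap, system$threshold,
                              system$const1_units)
  data.frame(r_nm = geom$r_nm, thetaT = geom$thetaT, thetaD = geom$thetaD,
             thetaA = geom$thetaA, kappa = kappa, QR_hz = QR, ER_hz = ER,
             gamma_d_hz = ER - QR, TrE = eff$TrE, TrQ = eff$TrQ,
             tau_ns = lt$tau_ns, branch = lt$branch,
             overlap = system$overlap, Jfp = system$Jfp,
             degenerate = eff$degenerate)
}
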
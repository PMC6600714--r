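# Spectrum construction, analytic cross-sections, lineshapes, overlap
# quantities and CSV round trips.

test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(c(400, 500), c(0, 1)), "mef_spectrum")
  expect_error(spectrum(500, 1), "at least 2")
  expect_error(spectrum(c(500, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(400, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(400, 500), c(-1, 1)), "nonnegative")
  expect_error(spectrum(c(400, 500), c(NaN, 1)), "finite")
})

test_that("Gans cross-sections reduce to the Rayleigh sphere at h = 2R", {
  pm <- drude_lorentz_permittivity("Au")
  grid <- seq(400, 900, by = 2)
  cs <- ellipsoid_cross_sections(20, 10, pm, grid)
  ray <- oracle_rayleigh_sphere(10, pm, grid)
  expect_lt(max(abs(cs$absorption$value - ray$absorption) /
                  ray$absorption), 1e-10)
  expect_lt(max(abs(cs$scattering$value - ray$scattering) /
                  ray$scattering), 1e-10)
})

test_that("index-matched particle has vanishing cross-sections", {
  pm <- tabulated_permittivity(c(300, 1000), rep(1.33^2, 2), c(0, 0))
  cs <- ellipsoid_cross_sections(40, 10, pm, seq(400, 800, 10))
  expect_true(all(cs$absorption$value == 0))
  expect_true(all(cs$scattering$value == 0))
})

test_that("rod longitudinal resonance is red-shifted and matches the dense polarizability argmax", {
  pm <- drude_lorentz_permittivity("Au")
  grid <- seq(400, 900, by = 1)
  rod <- ellipsoid_cross_sections(40, 10, pm, grid,
                                  orientation = "longitudinal")
  sphere <- ellipsoid_cross_sections(20, 10, pm, grid)
  rod_peak <- grid[which.max(rod$absorption$value)]
  sphere_peak <- grid[which.max(sphere$absorption$value)]
  expect_gt(rod_peak, sphere_peak)
  # dense-grid argmax of Im(longitudinal polarizability); the k = 2*pi*n/lambda
  # weighting of the cross-section shifts the peak by under a nanometre
  dense <- seq(400, 900, by = 0.1)
  eps <- permittivity_eval(pm, dense)
  eps_m <- pm$n_med^2
  e2 <- 1 - (20 / 40)^2
  e <- sqrt(e2)
  L1 <- ((1 - e2) / e2) * (-1 + log((1 + e) / (1 - e)) / (2 * e))
  alpha <- (eps - eps_m) / (eps_m + L1 * (eps - eps_m))
  expect_lt(abs(rod_peak - dense[which.max(Im(alpha))]), 3)
})

test_that("cross-sections scale with particle volume at fixed aspect ratio", {
  pm <- drude_lorentz_permittivity("Ag")
  grid <- seq(350, 700, by = 5)
  small <- ellipsoid_cross_sections(40, 10, pm, grid,
                                    orientation = "longitudinal")
  # double the volume: scale both axes by 2^(1/3)
  s <- 2^(1 / 3)
  big <- ellipsoid_cross_sections(40 * s, 10 * s, pm, grid,
                                  orientation = "longitudinal")
  expect_lt(max(abs(big$absorption$value - 2 * small$absorption$value) /
                  (2 * small$absorption$value)), 1e-9)
})

test_that("ellipsoid_cross_sections rejects bad geometry and wavelengths", {
  pm <- drude_lorentz_permittivity("Au")
  expect_error(ellipsoid_cross_sections(-1, 10, pm, 400:500), "positive")
  expect_error(ellipsoid_cross_sections(15, 10, pm, 400:500), ">= 2R")
  expect_error(ellipsoid_cross_sections(40, 10, pm, seq(100, 500, 10)),
               "support")
})

test_that("dye lineshapes are unit-area with the peak at the nearest grid point", {
  grid <- seq(400, 700, by = 1)
  for (shape in c("gaussian", "lognormal")) {
    s <- dye_lineshape(520, 40, shape, grid)
    expect_equal(trapz_area <- spectrum_area(s), 1, tolerance = 1e-9)
    expect_equal(s$wavelength_nm[which.max(s$value)], 520)
  }
  g <- dye_lineshape(520, 40, "gaussian", grid)
  # closed-form Gaussian ratio survives normalization
  expect_equal(g$value[grid == 540] / g$value[grid == 520],
               exp(-4 * log(2) * (20 / 40)^2), tolerance = 1e-9)
  expect_error(dye_lineshape(300, 40, "gaussian", grid), "outside")
  expect_error(dye_lineshape(520, -1, "gaussian", grid), "positive")
})

test_that("overlap_ratio obeys its bounds, symmetry and scale invariances", {
  grid <- seq(380, 700, by = 1)
  s1 <- dye_lineshape(500, 40, "gaussian", grid)
  s2 <- dye_lineshape(560, 40, "gaussian", grid)
  expect_equal(overlap_ratio(s1, s1), 1.0)
  # disjoint supports
  b1 <- spectrum(c(400, 401, 449, 450), c(0, 1, 1, 0))
  b2 <- spectrum(c(600, 601, 649, 650), c(0, 1, 1, 0))
  expect_equal(overlap_ratio(b1, b2), 0.0)
  v <- overlap_ratio(s1, s2)
  expect_gte(v, 0); expect_lte(v, 1)
  # symmetric after peak normalization when both are lineshapes of equal width
  expect_equal(overlap_ratio(s2, s1), v, tolerance = 1e-12)
  # invariant to positive scaling of either argument
  s1b <- spectrum(grid, s1$value * 37.5)
  expect_equal(overlap_ratio(s1b, s2), v, tolerance = 1e-12)
  expect_error(overlap_ratio(s1, spectrum(grid, rep(0, length(grid)))),
               "identically zero")
})

test_that("overlap_ratio matches the dense-grid min-overlap oracle", {
  grid <- seq(380, 700, by = 1)
  s1 <- dye_lineshape(500, 40, "gaussian", grid)
  s2 <- dye_lineshape(560, 40, "gaussian", grid)
  # frozen from the 0.01 nm dense-grid evaluation of the same formula
  expect_equal(oracle_overlap_gaussians(500, 40, 560, 40, c(380, 700)),
               0.0773765603, tolerance = 1e-6)
  # the 1 nm working grid agrees to trapezoid-discretization accuracy
  expect_equal(overlap_ratio(s1, s2), 0.0773765603, tolerance = 2e-3)
  # and re-sampling the lineshapes on the dense grid closes the gap
  dense <- seq(380, 700, by = 0.01)
  expect_equal(overlap_ratio(dye_lineshape(500, 40, "gaussian", dense),
                             dye_lineshape(560, 40, "gaussian", dense)),
               0.0773765603, tolerance = 1e-6)
})

test_that("Jfp: invariances, disjoint spectra, sifting limit, dense oracle", {
  grid <- seq(380, 700, by = 1)
  em <- dye_lineshape(560, 40, "gaussian", grid)
  sig <- spectrum(grid, exp(-4 * log(2) * ((grid - 530) / 50)^2) * 20,
                  "cross_section")
  j <- overlap_integral_jfp(sig, em)
  # frozen from the 0.01 nm dense-grid quadrature of the same formula
  expect_equal(j, 7.2398475e17, tolerance = 1e-3)
  expect_equal(j, oracle_jfp_dense(sig, em), tolerance = 1e-3)
  # scale invariance in the emission, linear scaling in 1/C and 1/l
  em_scaled <- spectrum(grid, em$value * 123)
  expect_equal(overlap_integral_jfp(sig, em_scaled), j, tolerance = 1e-12)
  expect_equal(overlap_integral_jfp(sig, em, C_NR_molar = 2e-9), j / 2,
               tolerance = 1e-12)
  expect_equal(overlap_integral_jfp(sig, em, l_cm = 4), j / 4,
               tolerance = 1e-12)
  # disjoint supports give exactly zero
  b1 <- spectrum(c(400, 401, 449, 450), c(0, 1, 1, 0), "cross_section")
  expect_equal(overlap_integral_jfp(b1, spectrum(c(600, 601, 649, 650),
                                                 c(0, 1, 1, 0))), 0)
  # sifting limit: a narrowing box at 540 tends to E_hat(540) * 540^4 / (C*l)
  e_hat <- em$value / spectrum_area(em)
  target <- e_hat[grid == 540] * 540^4 / 1e-9
  for (w in c(4, 2, 1)) {
    box <- spectrum(c(540 - w / 2, 540, 540 + w / 2), c(1, 1, 1),
                    "cross_section")
    expect_equal(overlap_integral_jfp(box, em), target,
                 tolerance = 0.02 * w)
  }
  expect_error(overlap_integral_jfp(spectrum(grid, rep(0, length(grid)),
                                             "cross_section"), em),
               "identically zero")
})

test_that("spectrum CSV round-trips at full precision and names bad lines", {
  s <- spectrum(c(400.123456789, 500.5, 601.25),
                c(0.123456789012345, 2.5, 0), kind = "cross_section")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_identical(s2$wavelength_nm, s$wavelength_nm)
  expect_identical(s2$value, s$value)
  expect_identical(s2$kind, "cross_section")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "500,1", "400,1"), bad)
  expect_error(read_spectrum_csv(bad), "strictly increasing")

  # comment + header occupy lines 1-2, so the third data row is line 5
  writeLines(c("# kind=lineshape", "wavelength_nm,value",
               "400,1", "410,2", "420,-3"), bad)
  expect_error(read_spectrum_csv(bad), "line 5")

  writeLines(c("wavelength_nm,value", "400,1,9"), bad)
  expect_error(read_spectrum_csv(bad), "line 2")
  expect_error(read_spectrum_csv("/nonexistent/spectrum.csv"), "no such")
})
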
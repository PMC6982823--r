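test_that("Reynolds number follows from the superficial velocity", {
  sys <- toy_system(Q = 1.68e-4, mu_f = 8.18e-5)
  d_bed <- 0.0303
  u <- 1.68e-4 / (857.2 * pi * d_bed^2 / 4)
  re_oracle <- 857.2 * u * 220e-6 / 8.18e-5
  expect_equal(suppressWarnings(reynolds(sys, d_bed)), re_oracle,
               tolerance = 1e-12)
  expect_warning(reynolds(sys, d_bed), "validity window")
  # linear in Q at fixed geometry
  sys2 <- toy_system(Q = 2 * 1.68e-4, mu_f = 8.18e-5)
  expect_equal(suppressWarnings(reynolds(sys2, d_bed)), 2 * re_oracle)
  expect_error(reynolds(sys, -1), "> 0")
})

test_that("default bed geometry reproduces the laboratory vessel", {
  d <- bed_diameter_default(0.023)
  expect_equal(d, (4 * (0.023 / 291) / (pi * 3.6))^(1 / 3))
  expect_equal(d, 0.0303, tolerance = 2e-3)
})

test_that("Schmidt number definition, scaling, and validity flag", {
  sc <- suppressWarnings(schmidt(8.18e-5, 857.2, 9.06e-9))
  expect_equal(sc, 8.18e-5 / (857.2 * 9.06e-9), tolerance = 1e-12)
  expect_equal(sc, 10.53, tolerance = 1e-3)
  expect_equal(suppressWarnings(schmidt(8.18e-5, 857.2, 2 * 9.06e-9)),
               sc / 2)
  expect_warning(schmidt(8.18e-5, 857.2, 5e-9), "validity window")  # Sc > 12
  expect_error(schmidt(8.18e-5, 857.2, 0), "> 0")
})

test_that("Sherwood power law evaluates and is monotone", {
  corr <- sherwood_correlation(0.0349, 0.58)
  expect_equal(sherwood(1, 1, corr), 0.0349)
  expect_equal(sherwood(27, 8, corr), 0.0349 * 27^0.58 * 8^(1 / 3),
               tolerance = 1e-12)
  expect_equal(sherwood(27, 8, corr), 0.472, tolerance = 1e-3)
  expect_lt(sherwood(10, 5, corr), sherwood(20, 5, corr))
  expect_lt(sherwood(10, 5, corr), sherwood(10, 10, corr))
  expect_error(sherwood_correlation(0.1, 0.3), "0.5, 0.8")
})

test_that("film coefficient and diffusivity round-trip exactly", {
  expect_equal(kf_from_sherwood(1, 1e-9, 1e-4), 1e-5)
  set.seed(3)
  for (i in 1:20) {
    Sh <- runif(1, 0.1, 10); D <- 10^runif(1, -10, -8); dp <- 10^runif(1, -5, -3)
    expect_equal(dab_from_kf(kf_from_sherwood(Sh, D, dp), Sh, dp), D,
                 tolerance = 1e-15)
  }
})

test_that("spheres rule gives both interfacial-area conventions", {
  expect_equal(a0_spheres(600e-6, 0.5), 5000)
  expect_equal(a0_spheres(600e-6, basis = "particle"), 10000)
  expect_gt(a0_spheres(200e-6, 0.5), a0_spheres(600e-6, 0.5))
  expect_error(a0_spheres(600e-6, basis = "bed"), "eps")
})

test_that("dense-gas diffusivity has the right order and density trend", {
  d_hi <- dab_catchpole_king(313.15, 857.2)
  d_lo <- suppressWarnings(dab_catchpole_king(313.15, 277.9))
  # order-of-magnitude agreement with tabulated first-approach values
  expect_gt(d_hi, 9.06e-9 / 3); expect_lt(d_hi, 9.06e-9 * 3)
  expect_gt(d_lo, 40.2e-9 / 3); expect_lt(d_lo, 40.2e-9 * 3)
  # decreasing in density at fixed temperature
  rho <- seq(500, 900, 50)
  expect_true(all(diff(dab_catchpole_king(313.15, rho)) < 0))
  expect_warning(dab_catchpole_king(313.15, 277.9), "validity")
})

test_that("Sherwood calibration recovers exact generating parameters", {
  corr <- sherwood_correlation(0.0349, 0.58)
  # two exact points: interpolation is exact
  p2 <- data.frame(Re = c(5, 40), Sc = c(4, 9))
  p2$Sh <- sherwood(p2$Re, p2$Sc, corr)
  expect_equal(unname(coef(fit_sherwood(p2))[1:2]), c(0.0349, 0.58),
               tolerance = 1e-12)
  # ten noiseless points
  set.seed(5)
  p10 <- data.frame(Re = exp(runif(10, log(2), log(60))),
                    Sc = runif(10, 2, 12))
  p10$Sh <- sherwood(p10$Re, p10$Sc, corr)
  f10 <- fit_sherwood(p10)
  expect_equal(f10$correlation$c0, 0.0349, tolerance = 1e-10)
  expect_equal(f10$correlation$c1, 0.58, tolerance = 1e-10)
  expect_equal(f10$r2_log, 1, tolerance = 1e-12)
  expect_error(fit_sherwood(data.frame(Re = c(5, 5), Sc = c(3, 4),
                                       Sh = c(1, 1))), "degenerate")
})

test_that("fitted Reynolds exponent never escapes its admissible interval", {
  set.seed(9)
  for (gen_c1 in c(0.2, 0.95)) {   # truths outside the box force clipping
    pts <- data.frame(Re = exp(runif(12, log(2), log(60))),
                      Sc = runif(12, 2, 12))
    pts$Sh <- 0.05 * pts$Re^gen_c1 * pts$Sc^(1 / 3) *
      exp(rnorm(12, 0, 0.05))
    f <- fit_sherwood(pts)
    expect_gte(f$correlation$c1, 0.5)
    expect_lte(f$correlation$c1, 0.8)
    expect_true(f$clipped)
    expect_identical(f$correlation$c2, 1 / 3)
  }
})

test_that("Sherwood calibration is scale-equivariant in the prefactor", {
  corr <- sherwood_correlation(0.04, 0.65)
  set.seed(6)
  pts <- data.frame(Re = exp(runif(8, log(2), log(60))), Sc = runif(8, 2, 12))
  pts$Sh <- sherwood(pts$Re, pts$Sc, corr) * exp(rnorm(8, 0, 0.03))
  f1 <- fit_sherwood(pts)
  pts2 <- pts; pts2$Sh <- 3 * pts$Sh
  f2 <- fit_sherwood(pts2)
  expect_equal(f2$correlation$c0, 3 * f1$correlation$c0, tolerance = 1e-10)
  expect_equal(f2$correlation$c1, f1$correlation$c1, tolerance = 1e-12)
})
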
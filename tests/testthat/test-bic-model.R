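test_that("dimensionless time is the scaled-time quotient, linear in t", {
  sys <- toy_system()
  expect_equal(dimensionless_time(0, sys), 0)
  # direct arithmetic: 3600 * 1e-4 * 1e-3 / (0.023 * 0.003)
  expect_equal(dimensionless_time(3600, sys),
               3600 * 1e-4 * 1e-3 / (0.023 * 0.003), tolerance = 1e-12)
  expect_equal(dimensionless_time(7200, sys),
               2 * dimensionless_time(3600, sys))
  expect_error(dimensionless_time(-1, sys), "non-negative")
})

test_that("transfer groups follow their defining quotients and scale as 1/Q", {
  sys <- toy_system(Q = 1.67e-4, rho_s = 1400, eps = 0.53, rho_f = 857.2)
  p <- bic_parameters(G = 0.5, ksa0 = 1e-5, kfa0 = 0.02)
  zy <- transfer_groups(sys, p)
  expect_equal(zy[["Z"]],
               0.023 * 0.02 * 857.2 / (1.67e-4 * 0.47 * 1400),
               tolerance = 1e-12)
  expect_equal(zy[["Y"]],
               0.023 * 1e-5 * 0.003 / (1.67e-4 * 0.47 * 1e-3),
               tolerance = 1e-12)
  sys2 <- toy_system(Q = 2 * 1.67e-4, rho_s = 1400)
  zy2 <- transfer_groups(sys2, p)
  expect_equal(zy2[["Z"]], zy[["Z"]] / 2)
  expect_equal(zy2[["Y"]], zy[["Y"]] / 2)
  expect_error(bic_parameters(G = 0.5, ksa0 = 1e-5, kfa0 = 0),
               "'kfa0' must be > 0")
})

test_that("third-period onset has its closed form and boundary identity", {
  expect_equal(psi_k(0, 2, 3), 0)
  expect_equal(psi_k(1, 2, 3), 1.5, tolerance = 1e-14)  # 1/2 + ln(e^3)/3
  d <- draw_gzy(200, seed = 7)
  for (i in seq_len(nrow(d))) {
    pk <- psi_k(d$G[i], d$Z[i], d$Y[i])
    expect_gte(pk, d$G[i] / d$Z[i])
    expect_lt(abs(h_k(pk, d$G[i], d$Z[i], d$Y[i]) - 1), 1e-12)
    expect_lt(abs(h_k(d$G[i] / d$Z[i], d$G[i], d$Z[i], d$Y[i])), 1e-12)
  }
})

test_that("boundary coordinate matches its closed form and rejects bad input", {
  # G = 1, Y = 2, psi - G/Z = 0.5 -> 0.5 * ln(1 + (e - 1)) = 0.5
  expect_equal(h_k(1, 1, 2, 2), 0.5, tolerance = 1e-14)
  expect_error(h_k(0.1, 0.5, 2, 2), "within")
  expect_error(h_k(10, 0.5, 2, 2), "within")
  expect_error(h_k(0.5, 0, 2, 2), "'G' must be > 0")
  # monotone in psi
  psi <- seq(0.25, psi_k(0.5, 2, 3), length.out = 50)
  expect_true(all(diff(h_k(psi, 0.5, 2, 3)) > 0))
})

test_that("the piecewise solution agrees with naive branch formulas inside each period", {
  d <- draw_gzy(50, seed = 11)
  for (i in seq_len(nrow(d))) {
    G <- d$G[i]; Z <- d$Z[i]; Y <- d$Y[i]
    gz <- G / Z; pk <- psi_k(G, Z, Y)
    p1 <- gz * 0.5
    p2 <- gz + (pk - gz) * 0.5
    p3 <- pk + 0.7
    expect_equal(extraction_fraction(p1, G, Z, Y), branch1(p1, G, Z, Y),
                 tolerance = 1e-12)
    expect_equal(extraction_fraction(p2, G, Z, Y), branch2(p2, G, Z, Y),
                 tolerance = 1e-12)
    expect_equal(extraction_fraction(p3, G, Z, Y), branch3(p3, G, Z, Y),
                 tolerance = 1e-12)
  }
})

test_that("extraction fraction is continuous at both period boundaries", {
  d <- draw_gzy(1000, seed = 13)
  gap1 <- gap2 <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    G <- d$G[i]; Z <- d$Z[i]; Y <- d$Y[i]
    gz <- G / Z; pk <- psi_k(G, Z, Y)
    gap1[i] <- abs(branch1(gz, G, Z, Y) - branch2(gz, G, Z, Y))
    gap2[i] <- abs(branch2(pk, G, Z, Y) - branch3(pk, G, Z, Y))
  }
  expect_lt(max(gap1), 1e-10)
  expect_lt(max(gap2), 1e-10)
})

test_that("extraction fraction is bounded, monotone, zero at zero, one in the limit", {
  d <- draw_gzy(100, seed = 17)
  for (i in seq_len(nrow(d))) {
    G <- d$G[i]; Z <- d$Z[i]; Y <- d$Y[i]
    pk <- psi_k(G, Z, Y)
    psi <- c(0, sort(runif(80, 0, pk * 2)), pk + 50 / Y)
    e <- extraction_fraction(psi, G, Z, Y)
    expect_equal(e[1], 0)
    expect_true(all(diff(e) >= -1e-13))
    expect_true(all(e >= 0 & e <= 1))
    expect_lt(abs(e[length(e)] - 1), 1e-10)
  }
})

test_that("early-stage slope equals 1 - exp(-Z) (mass rate Q ys (1-exp(-Z)))", {
  d <- draw_gzy(30, seed = 19)
  for (i in seq_len(nrow(d))) {
    G <- d$G[i]; Z <- d$Z[i]; Y <- d$Y[i]
    gz <- G / Z
    h <- gz * 1e-6
    fd <- (extraction_fraction(gz * 0.5 + h, G, Z, Y) -
             extraction_fraction(gz * 0.5, G, Z, Y)) / h
    expect_equal(fd, 1 - exp(-Z), tolerance = 1e-6)
  }
})

test_that("G = 1 collapses to two periods and G = 0 to pure diffusion control", {
  Z <- 2; Y <- 3
  pk1 <- psi_k(1, Z, Y)
  expect_equal(pk1, 1 / Z + 1)           # ln(e^Y)/Y = 1
  expect_equal(extraction_fraction(pk1 + 0.5, 1, Z, Y), 1)  # (1-G) term dies
  # G = 0: immediately diffusion-limited, e = 1 - ln(1 + (e^Y - 1) e^{-Y psi})/Y
  psi <- c(0, 0.4, 2)
  expect_equal(extraction_fraction(psi, 0, Z, Y),
               1 - log(1 + (exp(Y) - 1) * exp(-Y * psi)) / Y,
               tolerance = 1e-12)
})

test_that("simulated curves scale the fraction by the extractable load", {
  sys <- toy_system()
  p <- bic_parameters(0.5, 5e-5, 2e-3)
  expect_equal(simulate_curve(0, sys, p)$masses, 0)
  cv <- simulate_curve(seq(0, 4e4, 2e3), sys, p)
  expect_true(all(diff(cv$masses) >= -1e-15))
  expect_identical(cv$provenance, "simulated")
  far <- simulate_curve(1e9, sys, p)$masses
  expect_equal(far, sys$N * sys$x0, tolerance = 1e-9)
  expect_error(simulate_curve(c(3, 2, 1), sys, p), "increasing")
})

test_that("gravimetric yield is the percentage quotient", {
  expect_equal(yield_percent(0, 23e-3), 0)
  expect_equal(yield_percent(0.0655e-3, 23e-3), 0.285, tolerance = 1e-3)
  expect_equal(yield_percent(23e-3, 23e-3), 100)
  expect_error(yield_percent(1, 0), "must be > 0")
})
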
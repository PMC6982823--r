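test_that("factor coding maps levels to the unit interval and inverts", {
  expect_equal(code_factors(c(80, 220), 80, 220), c(-1, 1))
  expect_equal(code_factors(180, 80, 220), 0.4286, tolerance = 1e-4)
  v <- c(85, 117, 203)
  expect_equal(decode_factors(code_factors(v, 80, 220), 80, 220), v)
  expect_warning(code_factors(230, 80, 220), "outside")
})

test_that("the case-study OLS fit reproduces the published coefficients", {
  fit <- fit_rsm(lentiscus_design())
  cf <- coef(fit)
  expect_lt(abs(cf[["a0"]] - 0.183), 5e-4)
  expect_lt(abs(cf[["a1"]] - 0.084), 5e-4)
  expect_lt(abs(cf[["a23"]] - 0.019), 5e-4)
  expect_lt(abs(fit$coefficients["a1", "t"] - 3.71), 5e-3)
  expect_lt(abs(fit$r2 - 0.912), 1e-3)
  # inference bookkeeping: df = n - 7 = 3, stars at the stated cutpoints
  # (the intercept's p = 0.0011 earns two stars under p < 0.01)
  expect_equal(fit$lm$df.residual, 3)
  expect_lt(fit$coefficients["a0", "p"], 0.01)
  expect_identical(as.character(fit$coefficients["a0", "stars"]), "**")
  expect_identical(as.character(fit$coefficients["a1", "stars"]), "*")
})

test_that("exact synthetic yields are interpolated to machine precision", {
  a <- c(a0 = 0.2, a1 = 0.08, a2 = -0.01, a3 = 0.005, a12 = -0.02,
         a13 = 0.015, a23 = 0.01)
  d <- gen_doe(a, noise_sigma = 0)
  fit <- fit_rsm(d)
  expect_equal(coef(fit), a, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("OLS residuals are orthogonal to every design column", {
  fit <- fit_rsm(lentiscus_design())
  X <- stats::model.matrix(fit$lm)
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-10)
})

test_that("predicted R-squared never exceeds R-squared", {
  fit <- fit_rsm(lentiscus_design())
  expect_lte(fit$r2_predicted, fit$r2)
  set.seed(41)
  for (i in 1:10) {
    d <- lentiscus_design_coded()
    d$yield <- rnorm(nrow(d), 0.2, 0.05)
    f <- fit_rsm(d)
    expect_lte(f$r2_predicted, f$r2)
  }
})

test_that("model reduction keeps only the pressure term on the case study", {
  fit <- fit_rsm(lentiscus_design())
  red <- reduce_model(fit)
  expect_identical(red$terms, "a1")
  expect_equal(unname(red$coefficients),
               unname(coef(fit)[c("a0", "a1")]), tolerance = 1e-12)
  expect_match(red$equation, "^YD = 0.183 \\+ 0.084\\*x1$")
  full <- reduce_model(fit, alpha = 1)
  expect_length(full$terms, 6)
})

test_that("model reduction retains nothing at about the type-I rate under the null", {
  nret <- sapply(1:200, function(s) {
    d <- gen_doe(c(0.2, 0, 0, 0, 0, 0, 0), noise_sigma = 0.02,
                 seed = 1000 + s)
    length(reduce_model(fit_rsm(d))$terms)
  })
  # 6 tests at alpha = 0.05 -> about 0.3 retained terms per design
  expect_gt(mean(nret), 0.05)
  expect_lt(mean(nret), 0.7)
})

test_that("design-column correlations: identity on orthogonal factorials, published values on the case study", {
  C_orth <- coef_correlations(full_factorial_design())
  expect_equal(unname(C_orth), diag(6), tolerance = 1e-12)
  C <- coef_correlations(lentiscus_design())
  expect_equal(C["a3", "a23"], 0.4994, tolerance = 1e-4)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 6))
  # every entry matches the bundled published matrix at its printed precision
  expect_lt(max(abs(C - lentiscus_coef_correlation())), 5.1e-5)
})

test_that("column correlations ignore the response and factor scale", {
  d <- lentiscus_design()
  C1 <- coef_correlations(d)
  d$yield <- NULL                      # response plays no role
  d2 <- d; d2$x3 <- 2 * d2$x3          # rescaling a factor column
  expect_equal(coef_correlations(d2), C1, tolerance = 1e-12)
})

test_that("band percentage counts the off-diagonal pairs", {
  expect_equal(correlation_band_percent(diag(6)), 0)
  expect_equal(correlation_band_percent(lentiscus_coef_correlation()), 87)
  expect_equal(correlation_band_percent(lentiscus_coef_correlation(),
                                        band = c(0, 1)), 100)
})

test_that("exchange algorithm solves the enumerable design and never worsens", {
  # 1-factor linear model, candidates {-1, 0, 1}, k = 2: optimum is {-1, +1}
  cand <- data.frame(x = c(-1, 0, 1))
  sel <- d_optimal_select(cand, 2, formula = ~ x)
  expect_identical(cand$x[sel$indices], c(-1, 1))
  # exhaustive enumeration oracle
  combs <- utils::combn(3, 2)
  lds <- apply(combs, 2, function(ix)
    determinant(crossprod(cbind(1, cand$x[ix])), TRUE)$modulus)
  expect_equal(sel$logdet, max(as.numeric(lds)), tolerance = 1e-12)
  expect_true(all(diff(sel$logdet_trace) >= -1e-12))
  # full factorial, k = n: the full set is a fixed point
  ff <- full_factorial_design()
  sel_all <- d_optimal_select(ff, nrow(ff))
  expect_identical(sel_all$indices, seq_len(nrow(ff)))
  expect_error(d_optimal_select(ff, 3), "at least")
})

test_that("surface grids are flat for constant models and peak at the pressure corner", {
  flat <- fit_rsm(gen_doe(c(0.2, 0, 0, 0, 0, 0, 0), noise_sigma = 0))
  g0 <- surface_grid(flat, c("x1", "x2"), fixed = 0)
  expect_equal(diff(range(g0$yield)), 0, tolerance = 1e-12)
  fit <- fit_rsm(lentiscus_design())
  g <- surface_grid(fit, c("x1", "x2"), fixed = -1)
  top <- g[which.max(g$yield), ]
  expect_equal(c(top$x1, top$x2), c(1, -1))
  # exchangeable synthetic model: permuting the factor pair permutes nothing
  sym <- fit_rsm(gen_doe(c(0.2, 0.05, 0.05, 0.05, 0.01, 0.01, 0.01),
                         design = full_factorial_design(), noise_sigma = 0))
  g12 <- surface_grid(sym, c("x1", "x2"), fixed = 0.3)
  g23 <- surface_grid(sym, c("x2", "x3"), fixed = 0.3)
  expect_equal(g12$yield, g23$yield, tolerance = 1e-12)
})
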
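# Small builders shared across the test files.

toy_system <- function(N = 0.023, x0 = 0.003, ys = 1e-3, Q = 1e-4,
                       eps = 0.53, rho_s = NULL, rho_f = 857.2,
                       d_p = 220e-6, mu_f = 8.18e-5, ...) {
  if (is.null(rho_s))
    extraction_system(N = N, x0 = x0, ys = ys, Q = Q, eps = eps,
                      rho_bulk = 291, rho_f = rho_f, d_p = d_p,
                      mu_f = mu_f, ...)
  else
    extraction_system(N = N, x0 = x0, ys = ys, Q = Q, eps = eps,
                      rho_s = rho_s, rho_f = rho_f, d_p = d_p,
                      mu_f = mu_f, ...)
}

# Independent re-implementation of the three branch formulas, used as the
# oracle for the piecewise solution (kept deliberately naive).
branch1 <- function(psi, G, Z, Y) psi * (1 - exp(-Z))
branch2 <- function(psi, G, Z, Y) {
  hk <- log(1 + (exp(Y * (psi - G / Z)) - 1) / G) / Y
  psi - (G / Z) * exp(Z * (hk - 1))
}
branch3 <- function(psi, G, Z, Y) {
  1 - log(1 + (exp(Y) - 1) * exp(Y * (G / Z - psi)) * (1 - G)) / Y
}

# random valid BIC parameter draws on a fixed seed
draw_gzy <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(G = runif(n, 0.02, 0.98),
             Z = exp(runif(n, log(0.1), log(10))),
             Y = exp(runif(n, log(0.05), log(20))))
}

full_factorial_design <- function() {
  d <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  d
}
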
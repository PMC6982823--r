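#' Dimensionless extraction time
#'
#' Scales clock time by the solvent's carrying capacity relative to the
#' initial solute load of the bed:
#' \deqn{\psi = t \, Q \, y_s / (N x_0).}
#'
#' @param t time in seconds (vectorised), non-negative.
#' @param system an [extraction_system()].
#' @return dimensionless time(s) `psi`.
#' @examples
#' sys <- extraction_system(N = 0.023, x0 = 0.003, ys = 1e-3, Q = 1e-4,
#'                          eps = 0.53, rho_bulk = 291, rho_f = 857.2,
#'                          d_p = 220e-6)
#' dimensionless_time(3600, sys)   # ~5.217
#' @export
dimensionless_time <- function(t, system) {
  stopifnot(inherits(system, "extraction_system"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  t * system$Q * system$ys / (system$N * system$x0)
}

#' Dimensionless external and internal transfer groups
#'
#' The two dimensionless groups of the broken-and-intact-cell model,
#' proportional to the external and internal volumetric mass-transfer
#' parameters:
#' \deqn{Z = N k_f a_0 \rho_f / (Q (1-\varepsilon) \rho_s), \quad
#'       Y = N k_s a_0 x_0 / (Q (1-\varepsilon) y_s).}
#'
#' @param system an [extraction_system()].
#' @param params a [bic_parameters()] object.
#' @return named numeric vector `c(Z = , Y = )`, both strictly positive.
#' @export
transfer_groups <- function(system, params) {
  stopifnot(inherits(system, "extraction_system"),
            inherits(params, "bic_parameters"))
  denom <- system$Q * (1 - system$eps)
  Z <- system$N * params$kfa0 * system$rho_f / (denom * system$rho_s)
  Y <- system$N * params$ksa0 * system$x0 / (denom * system$ys)
  c(Z = Z, Y = Y)
}

#' Onset of the diffusion-controlled third extraction period
#'
#' \deqn{\psi_k = G/Z + \frac{1}{Y}\ln\{1 + G\,(e^{Y} - 1)\}.}
#' At `psi_k` the broken-cell/intact-cell boundary reaches the bed outlet,
#' i.e. `h_k(psi_k) = 1` identically.
#'
#' @param G grinding efficiency in \[0,1\].
#' @param Z,Y the transfer groups, both > 0.
#' @return the dimensionless onset `psi_k`, always >= `G/Z`.
#' @export
psi_k <- function(G, Z, Y) {
  stopifnot(G >= 0, G <= 1, Z > 0, Y > 0)
  # log1p(G*expm1(Y)) computed stably for large Y: ln(1+G e^Y) ~ Y + ln(G)
  tail <- ifelse(Y > 700 & G > 0, Y + log(G), log1p(G * expm1(pmin(Y, 700))))
  G / Z + tail / Y
}

#' Dimensionless bed coordinate of the broken/intact boundary
#'
#' \deqn{h_k = \frac{1}{Y}\ln\left[1 + \frac{e^{Y(\psi - G/Z)} - 1}{G}\right]}
#' for `G/Z <= psi <= psi_k` and `G > 0`. Monotone increasing in `psi`, with
#' `h_k(G/Z) = 0` and `h_k(psi_k) = 1` (substituting the `psi_k` expression
#' makes the log argument `exp(Y)` exactly).
#'
#' @param psi dimensionless time(s) within `[G/Z, psi_k]`.
#' @inheritParams psi_k
#' @return the boundary coordinate(s) in \[0, 1\].
#' @export
h_k <- function(psi, G, Z, Y) {
  stopifnot(Z > 0, Y > 0)
  if (G <= 0) stop("'G' must be > 0 for the boundary coordinate",
                   call. = FALSE)
  pk <- psi_k(G, Z, Y)
  if (any(psi < G / Z - 1e-12) || any(psi > pk + 1e-12))
    stop("'psi' must lie within [G/Z, psi_k]", call. = FALSE)
  log1p(expm1(pmin(Y * (psi - G / Z), 700)) / G) / Y
}

#' Extracted fraction along the three-period analytical solution
#'
#' The cumulative extracted fraction `e = E/(N x0)` of the
#' broken-and-intact-cell model, as a piecewise analytical function of
#' dimensionless time:
#' \describe{
#'   \item{period 1 (`psi < G/Z`)}{`e = psi (1 - exp(-Z))` — the
#'     solubility-limited constant-extraction-rate period;}
#'   \item{period 2 (`G/Z <= psi < psi_k`)}{`e = psi - (G/Z) exp(Z (h_k - 1))`
#'     — broken-cell solute depletes progressively along the bed;}
#'   \item{period 3 (`psi >= psi_k`)}{
#'     `e = 1 - (1/Y) ln(1 + (exp(Y)-1) exp(Y(G/Z - psi)) (1-G))` — internal
#'     diffusion from intact cells controls the tail.}
#' }
#' Boundary points belong to the later branch; the three branches agree at
#' both boundaries to machine precision.
#'
#' @param psi dimensionless time(s), >= 0 (vectorised).
#' @inheritParams psi_k
#' @return extracted fraction(s) in \[0, 1\], continuous and non-decreasing.
#' @export
extraction_fraction <- function(psi, G, Z, Y) {
  stopifnot(G >= 0, G <= 1, Z > 0, Y > 0)
  if (any(psi < 0)) stop("'psi' must be non-negative", call. = FALSE)
  pk <- psi_k(G, Z, Y)
  gz <- G / Z
  e <- numeric(length(psi))
  b1 <- psi < gz
  b2 <- !b1 & psi < pk
  b3 <- psi >= pk
  if (any(b1)) e[b1] <- psi[b1] * (1 - exp(-Z))
  if (any(b2)) {
    hk <- h_k(psi[b2], G, Z, Y)
    e[b2] <- psi[b2] - gz * exp(Z * (hk - 1))
  }
  if (any(b3)) {
    # (e^Y - 1) e^{Y(G/Z - psi)} = (1 - e^{-Y}) e^{Y(1 + G/Z - psi)};
    # the combined exponent is bounded by -ln(G) for psi >= psi_k, so this
    # form cannot overflow where the original product would.
    arg <- (1 - exp(-Y)) * exp_clip(Y * (1 + gz - psi[b3])) * (1 - G)
    e[b3] <- 1 - log1p(arg) / Y
  }
  pmin(pmax(e, 0), 1)
}

#' Simulate a noise-free overall extraction curve
#'
#' Composes the dimensionless-time map, the transfer groups and the
#' three-period analytical solution into cumulative extract mass
#' `E(t) = N x0 e(psi(t))`.
#'
#' @param times strictly increasing, non-negative sample times (s).
#' @param system an [extraction_system()] (must have a finite `x0`).
#' @param params a [bic_parameters()] object.
#' @return an [extraction_curve()] with `provenance = "simulated"`.
#' @export
simulate_curve <- function(times, system, params) {
  stopifnot(inherits(system, "extraction_system"))
  if (is.na(system$x0))
    stop("'system$x0' must be set to simulate a curve", call. = FALSE)
  if (length(times) < 1 || any(times < 0) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("'times' must be strictly increasing and non-negative",
         call. = FALSE)
  zy <- transfer_groups(system, params)
  psi <- dimensionless_time(times, system)
  e <- extraction_fraction(psi, params$G, zy[["Z"]], zy[["Y"]])
  extraction_curve(times, system$N * system$x0 * e, system,
                   provenance = "simulated")
}

#' Gravimetric extraction yield
#'
#' `100 * mass_extract / mass_raw`, the mass percentage of feed recovered as
#' extract.
#'
#' @param mass_extract extract mass (kg), >= 0.
#' @param mass_raw raw feed mass (kg), > 0.
#' @return yield in percent.
#' @examples
#' yield_percent(0.0655e-3, 23e-3)  # ~0.285
#' @export
yield_percent <- function(mass_extract, mass_raw) {
  if (any(mass_raw <= 0)) stop("'mass_raw' must be > 0", call. = FALSE)
  if (any(mass_extract < 0)) stop("'mass_extract' must be >= 0", call. = FALSE)
  100 * mass_extract / mass_raw
}
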
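#' Physical constants for the solvent and the solute proxy
#'
#' Critical constants and molar masses used by the dense-gas diffusivity
#' correlation. The solute proxy is alpha-pinene, the major component of the
#' bundled leaf-oil case study; its critical volume is a Joback-type
#' literature estimate. `Dc` is the correlation's CO2 amplitude (m^2/s),
#' anchored so the solvent self-diffusivity term reproduces measured CO2
#' self-diffusion (about 2e-8 m^2/s at 313 K and 857 kg/m^3). These are
#' inputs, not fitted results.
#'
#' @format A list with components `co2` (`M` g/mol, `Tc` K, `Pc` bar,
#'   `rho_c` kg/m^3, `Vc` cm^3/mol, `Dc` m^2/s) and `alpha_pinene`
#'   (`M`, `Tc`, `Pc`, `Vc`).
#' @export
solute_constants <- list(
  co2 = list(M = 44.01, Tc = 304.13, Pc = 73.77, rho_c = 467.6,
             Vc = 94.07, Dc = 1.74e-8),
  alpha_pinene = list(M = 136.234, Tc = 632.0, Pc = 27.6, Vc = 504.0)
)

# Correlation validity window for the fitted Sherwood expression.
RE_RANGE <- c(2, 60)
SC_RANGE <- c(2, 12)

check_window <- function(value, range, label) {
  out <- value < range[1] | value > range[2]
  if (any(out))
    warning(sprintf("%s = %s outside the correlation validity window [%g, %g]",
                    label, paste(signif(value[out], 3), collapse = ", "),
                    range[1], range[2]), call. = FALSE)
  invisible(out)
}

#' Particle Reynolds number of the packed bed
#'
#' Superficial velocity `u = Q/(rho_f A)` with `A = pi d_bed^2/4`, then
#' `Re = rho_f u d_p / mu_f`. Values outside the fitted correlation's
#' validity window (2--60) raise a warning, not an error.
#'
#' @param system an [extraction_system()] with `mu_f` set.
#' @param bed_diameter internal bed diameter (m). Defaults to the geometry
#'   implied by the bed mass, a bulk density of 291 kg/m^3 and a
#'   height-to-diameter ratio of 3.6 (the laboratory vessel of the bundled
#'   case study).
#' @return the Reynolds number (dimensionless).
#' @export
reynolds <- function(system, bed_diameter = NULL) {
  stopifnot(inherits(system, "extraction_system"))
  if (is.na(system$mu_f)) stop("'mu_f' must be set", call. = FALSE)
  if (is.null(bed_diameter))
    bed_diameter <- bed_diameter_default(system$N)
  if (bed_diameter <= 0) stop("'bed_diameter' must be > 0", call. = FALSE)
  area <- pi * bed_diameter^2 / 4
  u <- system$Q / (system$rho_f * area)
  re <- system$rho_f * u * system$d_p / system$mu_f
  check_window(re, RE_RANGE, "Re")
  re
}

#' Default laboratory bed diameter from feed mass
#'
#' Bed volume `N/rho_bulk` shaped as a cylinder with `H/d = aspect`.
#'
#' @param N feed mass (kg).
#' @param rho_bulk bed bulk density (kg/m^3).
#' @param aspect height-to-diameter ratio.
#' @return bed diameter (m).
#' @export
bed_diameter_default <- function(N, rho_bulk = 291, aspect = 3.6) {
  stopifnot(N > 0, rho_bulk > 0, aspect > 0)
  (4 * (N / rho_bulk) / (pi * aspect))^(1 / 3)
}

#' Schmidt number
#'
#' `Sc = mu_f / (rho_f D_AB)`. Values outside the validity window (2--12)
#' raise a warning.
#'
#' @param mu_f dynamic viscosity (kg m^-1 s^-1).
#' @param rho_f fluid density (kg/m^3).
#' @param D_AB binary diffusion coefficient (m^2/s).
#' @return the Schmidt number.
#' @export
schmidt <- function(mu_f, rho_f, D_AB) {
  stopifnot(mu_f > 0, rho_f > 0)
  if (any(D_AB <= 0)) stop("'D_AB' must be > 0", call. = FALSE)
  sc <- mu_f / (rho_f * D_AB)
  check_window(sc, SC_RANGE, "Sc")
  sc
}

#' Sherwood number from a power-law correlation
#'
#' `Sh = c0 Re^c1 Sc^c2` with the Schmidt exponent fixed at 1/3, the
#' conventional form for forced-convection mass transfer in packed beds.
#'
#' @param Re,Sc Reynolds and Schmidt numbers (positive, vectorised).
#' @param corr a [sherwood_correlation()] or fitted [fit_sherwood()] object.
#' @return Sherwood number(s).
#' @export
sherwood <- function(Re, Sc, corr) {
  stopifnot(all(Re > 0), all(Sc > 0))
  corr <- as_sherwood_correlation(corr)
  corr$c0 * Re^corr$c1 * Sc^corr$c2
}

#' Construct a Sherwood correlation
#'
#' @param c0 prefactor (> 0).
#' @param c1 Reynolds exponent; the packed-bed literature constrains it to
#'   \[0.5, 0.8\].
#' @param c2 Schmidt exponent, fixed at 1/3.
#' @return an object of class `sherwood_correlation`.
#' @export
sherwood_correlation <- function(c0, c1, c2 = 1 / 3) {
  stopifnot(c0 > 0)
  if (c1 < 0.5 || c1 > 0.8)
    stop("'c1' must lie in [0.5, 0.8]", call. = FALSE)
  if (abs(c2 - 1 / 3) > 1e-12)
    stop("'c2' is fixed at 1/3", call. = FALSE)
  structure(list(c0 = c0, c1 = c1, c2 = 1 / 3),
            class = "sherwood_correlation")
}

as_sherwood_correlation <- function(x) {
  if (inherits(x, "sherwood_fit")) x$correlation
  else if (inherits(x, "sherwood_correlation")) x
  else stop("expected a 'sherwood_correlation' or 'sherwood_fit'",
            call. = FALSE)
}

#' @export
print.sherwood_correlation <- function(x, ...) {
  cat(sprintf("Sh = %.4g Re^%.3g Sc^(1/3)\n", x$c0, x$c1))
  invisible(x)
}

#' Convert between the film coefficient, Sherwood number and diffusivity
#'
#' Packed-bed convention with the particle diameter as characteristic
#' length: `kf = Sh D_AB / d_p`. `dab_from_kf()` is the exact inverse.
#'
#' @param Sh Sherwood number.
#' @param D_AB binary diffusion coefficient (m^2/s).
#' @param d_p particle diameter (m).
#' @param kf film mass-transfer coefficient (m/s).
#' @return `kf_from_sherwood()` the film coefficient (m/s);
#'   `dab_from_kf()` the diffusivity (m^2/s).
#' @export
kf_from_sherwood <- function(Sh, D_AB, d_p) {
  stopifnot(all(Sh > 0), all(D_AB > 0), all(d_p > 0))
  Sh * D_AB / d_p
}

#' @rdname kf_from_sherwood
#' @export
dab_from_kf <- function(kf, Sh, d_p) {
  stopifnot(all(kf > 0), all(Sh > 0), all(d_p > 0))
  kf * d_p / Sh
}

#' Specific interfacial area of a bed of spheres
#'
#' Default convention is the bed-volume basis `a0 = 6 (1 - eps)/d_p`; the
#' particle-volume basis `a0 = 6/d_p` is selectable. Only the lumped products
#' `kf a0` and `ks a0` are observable from extraction curves, so both
#' conventions are exposed.
#'
#' @param d_p particle diameter (m).
#' @param eps bed void fraction, required for the bed basis.
#' @param basis `"bed"` (default) or `"particle"`.
#' @return specific area (1/m).
#' @export
a0_spheres <- function(d_p, eps = NULL, basis = c("bed", "particle")) {
  basis <- match.arg(basis)
  stopifnot(all(d_p > 0))
  if (basis == "bed") {
    if (is.null(eps) || any(eps <= 0) || any(eps >= 1))
      stop("'eps' in (0,1) required for the bed-volume basis", call. = FALSE)
    6 * (1 - eps) / d_p
  } else {
    6 / d_p
  }
}

#' Dense-gas binary diffusion coefficient (Catchpole--King type)
#'
#' Corresponding-states estimate of the solute diffusivity in dense CO2:
#' \deqn{D_{11} = 5.152\, D_c\, T_r\, (\rho_r^{-2/3} - 0.4510), \qquad
#'       D_{AB} = D_{11} / X,}
#' where `T_r` and `rho_r` are the solvent reduced temperature and density
#' and the size--mass factor is
#' \deqn{X = \left[1 + (V_{c,2}/V_{c,1})^{1/3}\right]^2 \big/
#'       \left[4\sqrt{1 + M_1/M_2}\right].}
#' The reduced-density term makes the estimate decrease with solvent density;
#' reduced densities outside (1, 2.5) are flagged as extrapolation.
#'
#' @param T temperature (K).
#' @param rho_f solvent density (kg/m^3).
#' @param solute list with solute `M` (g/mol) and `Vc` (cm^3/mol); defaults
#'   to alpha-pinene.
#' @param solvent list of solvent constants; defaults to CO2.
#' @return the binary diffusion coefficient (m^2/s).
#' @examples
#' dab_catchpole_king(313.15, 857.2)  # order 1e-8 m^2/s
#' @export
dab_catchpole_king <- function(T, rho_f,
                               solute = solute_constants$alpha_pinene,
                               solvent = solute_constants$co2) {
  stopifnot(T > 0, all(rho_f > 0))
  Tr <- T / solvent$Tc
  rho_r <- rho_f / solvent$rho_c
  if (any(rho_r < 1 | rho_r > 2.5))
    warning("reduced density outside the correlation's validity (1, 2.5)",
            call. = FALSE)
  d11 <- 5.152 * solvent$Dc * Tr * (rho_r^(-2 / 3) - 0.4510)
  if (any(d11 <= 0))
    stop("reduced density too low: self-diffusivity term non-positive",
         call. = FALSE)
  X <- (1 + (solute$Vc / solvent$Vc)^(1 / 3))^2 /
    (4 * sqrt(1 + solvent$M / solute$M))
  d11 / X
}

#' External volumetric mass-transfer parameter from a Sherwood correlation
#'
#' Chains the transport conversions for the correlation-based estimation
#' route: diffusivity from the dense-gas correlation, Re and Sc from the bed
#' conditions, Sh from `corr`, then `kf a0 = (Sh D_AB / d_p) a0`.
#'
#' @param system an [extraction_system()] with `mu_f` set.
#' @param corr a [sherwood_correlation()] or [fit_sherwood()] result.
#' @param bed_diameter bed diameter (m); default as in [reynolds()].
#' @param a0_basis interfacial-area convention, see [a0_spheres()].
#' @param D_AB optionally override the correlation-estimated diffusivity.
#' @return `kfa0` (1/s).
#' @export
kfa0_from_correlation <- function(system, corr, bed_diameter = NULL,
                                  a0_basis = "bed", D_AB = NULL) {
  if (is.null(D_AB))
    D_AB <- dab_catchpole_king(system$T, system$rho_f)
  re <- suppressWarnings(reynolds(system, bed_diameter))
  sc <- suppressWarnings(schmidt(system$mu_f, system$rho_f, D_AB))
  sh <- sherwood(re, sc, corr)
  kf <- kf_from_sherwood(sh, D_AB, system$d_p)
  kf * a0_spheres(system$d_p, system$eps, basis = a0_basis)
}

#' Calibrate a Sherwood correlation from observed transport points
#'
#' Least squares in log space (a power law is linear in logs) of
#' `log(Sh / Sc^(1/3))` on `log(Re)`, with the Schmidt exponent held at 1/3.
#' If the unconstrained Reynolds exponent falls outside the admissible
#' interval \[0.5, 0.8\] it is clipped to the nearer bound and the prefactor
#' re-estimated conditionally.
#'
#' @param points a data frame with columns `Re`, `Sc`, `Sh` (>= 2 rows).
#' @return an object of class `sherwood_fit` with components `correlation`
#'   (a [sherwood_correlation()]), `r2_log` (coefficient of determination of
#'   the log-space fit), `clipped`, `n`, and `residuals_log`.
#' @export
fit_sherwood <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("Re", "Sc", "Sh") %in% names(points)))
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(points$Re <= 0 | points$Sc <= 0 | points$Sh <= 0))
    stop("Re, Sc, Sh must all be positive", call. = FALSE)
  lre <- log(points$Re)
  if (diff(range(lre)) < 1e-12)
    stop("degenerate points: all Re equal, the exponent is unidentifiable",
         call. = FALSE)
  lsh <- log(points$Sh) - log(points$Sc) / 3
  fit <- stats::lm(lsh ~ lre)
  c1 <- unname(stats::coef(fit)[2])
  clipped <- c1 < 0.5 || c1 > 0.8
  if (clipped) {
    c1 <- min(max(c1, 0.5), 0.8)
    lc0 <- mean(lsh - c1 * lre)
  } else {
    lc0 <- unname(stats::coef(fit)[1])
  }
  res <- lsh - (lc0 + c1 * lre)
  sst <- sum((lsh - mean(lsh))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  structure(list(correlation = sherwood_correlation(exp(lc0), c1),
                 r2_log = r2, clipped = clipped, n = nrow(points),
                 residuals_log = res),
            class = "sherwood_fit")
}

#' @export
print.sherwood_fit <- function(x, ...) {
  print(x$correlation)
  cat(sprintf("  fitted on %d points, log-space R^2 = %.4f%s\n", x$n,
              x$r2_log, if (x$clipped) " (Re exponent clipped)" else ""))
  invisible(x)
}

#' @export
coef.sherwood_fit <- function(object, ...) {
  c(c0 = object$correlation$c0, c1 = object$correlation$c1,
    c2 = object$correlation$c2)
}

#' @export
predict.sherwood_fit <- function(object, newdata, ...) {
  sherwood(newdata$Re, newdata$Sc, object$correlation)
}
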
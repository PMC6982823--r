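#' Define a packed-bed extraction run
#'
#' Collects the bed, feed, solvent and solubility constants that define one
#' supercritical CO2 extraction run. All quantities are SI.
#'
#' @param N feed mass of milled solid (kg).
#' @param x0 initial extractable-oil mass fraction of the solid
#'   (kg oil / kg solid). May be `NA` for measured curves whose total
#'   extractable fraction is unknown; [fit_bic()] then defaults it to the
#'   asymptotic extract mass divided by `N`.
#' @param ys oil solubility in the solvent (kg oil / kg CO2).
#' @param Q solvent mass flow rate (kg/s).
#' @param eps bed void fraction (dimensionless, in (0,1)).
#' @param rho_s true density of the solid (kg/m^3). Defaults to
#'   `rho_bulk/(1 - eps)` when `rho_bulk` is given instead.
#' @param rho_f solvent density at extraction conditions (kg/m^3).
#' @param d_p mean particle diameter (m).
#' @param T temperature (K).
#' @param P pressure (Pa).
#' @param mu_f solvent dynamic viscosity (kg m^-1 s^-1).
#' @param rho_bulk optional bed bulk density (kg/m^3), used to derive `rho_s`
#'   via the standard bed relation when `rho_s` is missing.
#'
#' @return An object of class `extraction_system` (a named list).
#' @examples
#' sys <- extraction_system(N = 0.023, x0 = 0.003, ys = 1e-3, Q = 1e-4,
#'                          eps = 0.53, rho_bulk = 291, rho_f = 857.2,
#'                          d_p = 220e-6, T = 313.15, P = 220e5, mu_f = 8.18e-5)
#' @export
extraction_system <- function(N, x0, ys, Q, eps, rho_s = NULL, rho_f,
                              d_p, T = 313.15, P = NA_real_,
                              mu_f = NA_real_, rho_bulk = NULL) {
  if (is.null(rho_s)) {
    if (is.null(rho_bulk))
      stop("either 'rho_s' or 'rho_bulk' must be given", call. = FALSE)
    rho_s <- rho_bulk / (1 - eps)
  }
  stopifnot(N > 0, ys > 0, Q > 0, eps > 0, eps < 1,
            rho_s > 0, rho_f > 0, d_p > 0)
  if (!is.na(x0) && (x0 <= 0 || x0 >= 1))
    stop("'x0' must lie in (0, 1)", call. = FALSE)
  structure(list(N = N, x0 = x0, ys = ys, Q = Q, eps = eps,
                 rho_s = rho_s, rho_f = rho_f, d_p = d_p,
                 T = T, P = P, mu_f = mu_f),
            class = "extraction_system")
}

#' @export
print.extraction_system <- function(x, ...) {
  cat("Packed-bed extraction system\n")
  cat(sprintf("  feed N = %g kg, x0 = %g, ys = %g kg/kg\n", x$N, x$x0, x$ys))
  cat(sprintf("  Q = %g kg/s, eps = %.3f, d_p = %g m\n", x$Q, x$eps, x$d_p))
  cat(sprintf("  rho_s = %.1f, rho_f = %.1f kg/m^3, T = %.2f K\n",
              x$rho_s, x$rho_f, x$T))
  invisible(x)
}

#' The three adjustable kinetic parameters of the BIC model
#'
#' @param G grinding efficiency: fraction of cells broken by milling,
#'   in \[0, 1\].
#' @param ksa0 internal (solid-phase) volumetric mass-transfer parameter
#'   (1/s), strictly positive.
#' @param kfa0 external (fluid-film) volumetric mass-transfer parameter
#'   (1/s), strictly positive.
#'
#' @return An object of class `bic_parameters`.
#' @examples
#' bic_parameters(G = 0.61, ksa0 = 7.01e-5, kfa0 = 1.72e-3)
#' @export
bic_parameters <- function(G, ksa0, kfa0) {
  stopifnot(is.finite(G), is.finite(ksa0), is.finite(kfa0))
  if (G < 0 || G > 1) stop("'G' must lie in [0, 1]", call. = FALSE)
  if (ksa0 <= 0) stop("'ksa0' must be > 0", call. = FALSE)
  if (kfa0 <= 0) stop("'kfa0' must be > 0", call. = FALSE)
  structure(list(G = G, ksa0 = ksa0, kfa0 = kfa0), class = "bic_parameters")
}

#' @export
print.bic_parameters <- function(x, ...) {
  cat(sprintf("BIC parameters: G = %.4g, ksa0 = %.4g 1/s, kfa0 = %.4g 1/s\n",
              x$G, x$ksa0, x$kfa0))
  invisible(x)
}

#' Cumulative extraction curve container
#'
#' @param times sample times (s), strictly increasing, first value >= 0.
#' @param masses cumulative extract mass (kg), same length as `times`.
#' @param system the [extraction_system()] the curve belongs to.
#' @param provenance one of `"measured"`, `"synthetic"`, `"simulated"`.
#'   Simulated (noise-free model) curves must be non-decreasing and bounded by
#'   `N * x0`; synthetic/measured curves carry weighing noise and are only
#'   required to be non-negative.
#'
#' @return An object of class `extraction_curve`.
#' @export
extraction_curve <- function(times, masses, system,
                             provenance = c("measured", "synthetic",
                                            "simulated")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(system, "extraction_system"),
            length(times) == length(masses), length(times) >= 1)
  if (times[1] < 0 || (length(times) > 1 && any(diff(times) <= 0)))
    stop("'times' must be strictly increasing and start at >= 0",
         call. = FALSE)
  if (any(masses < 0))
    stop("'masses' must be non-negative", call. = FALSE)
  if (provenance == "simulated") {
    if (any(diff(masses) < -1e-12))
      stop("simulated curves must be non-decreasing", call. = FALSE)
    if (!is.na(system$x0) && any(masses > system$N * system$x0 * (1 + 1e-9)))
      stop("simulated masses exceed the extractable load N*x0", call. = FALSE)
  }
  structure(list(times = as.numeric(times), masses = as.numeric(masses),
                 system = system, provenance = provenance),
            class = "extraction_curve")
}

#' @export
print.extraction_curve <- function(x, ...) {
  cat(sprintf("Extraction curve (%s): %d samples, t = %g..%g s, E_final = %g kg\n",
              x$provenance, length(x$times), min(x$times), max(x$times),
              x$masses[length(x$masses)]))
  invisible(x)
}

#' @export
plot.extraction_curve <- function(x, ...) {
  graphics::plot(x$times / 3600, x$masses * 1e3, xlab = "time (h)",
                 ylab = "cumulative extract (g)",
                 main = paste("Extraction curve,", x$provenance), ...)
  invisible(x)
}

#' @rdname extraction_curve
#' @param x an `extraction_curve`.
#' @param ... unused.
#' @export
as.data.frame.extraction_curve <- function(x, ...) {
  data.frame(time_s = x$times, extract_kg = x$masses)
}

#' Read and write extraction-curve CSV files
#'
#' The on-disk format is a two-column CSV with header `time_s,extract_kg`,
#' optionally preceded by `# key: value` metadata comment lines carrying the
#' system constants (`N_kg`, `x0`, `ys`, `Q_kg_s`, `pressure_bar`, `temp_C`,
#' `dp_um`, `eps`, `rho_f`, `rho_s`, `mu_f`, `provenance`).
#'
#' @param file path to a CSV file.
#' @param curve an [extraction_curve()].
#' @return `read_extraction_curve()` returns an `extraction_curve` (with a
#'   metadata-built system when the comment lines are present);
#'   `write_extraction_curve()` returns `file` invisibly.
#' @export
write_extraction_curve <- function(curve, file) {
  s <- curve$system
  meta <- c(N_kg = s$N, x0 = s$x0, ys = s$ys, Q_kg_s = s$Q,
            pressure_bar = if (is.na(s$P)) NA else s$P / 1e5,
            temp_C = s$T - 273.15, dp_um = s$d_p * 1e6, eps = s$eps,
            rho_f = s$rho_f, rho_s = s$rho_s, mu_f = s$mu_f)
  lines <- c(sprintf("# %s: %.15g", names(meta), meta),
             sprintf("# provenance: %s", curve$provenance),
             "time_s,extract_kg",
             sprintf("%.15g,%.15g", curve$times, curve$masses))
  write_atomic(lines, file)
  invisible(file)
}

#' @rdname write_extraction_curve
#' @export
read_extraction_curve <- function(file) {
  lines <- readLines(file)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  num <- function(k) if (is.null(meta[[k]])) NA_real_ else as.numeric(meta[[k]])
  dat <- utils::read.csv(text = lines[!is_meta])
  if (!all(c("time_s", "extract_kg") %in% names(dat)))
    stop("curve CSV must have columns 'time_s' and 'extract_kg'",
         call. = FALSE)
  sys <- extraction_system(
    N = num("N_kg"), x0 = num("x0"), ys = num("ys"), Q = num("Q_kg_s"),
    eps = num("eps"), rho_s = num("rho_s"), rho_f = num("rho_f"),
    d_p = num("dp_um") * 1e-6, T = num("temp_C") + 273.15,
    P = num("pressure_bar") * 1e5, mu_f = num("mu_f"))
  prov <- if (is.null(meta$provenance)) "measured" else meta$provenance
  extraction_curve(dat$time_s, dat$extract_kg, sys, provenance = prov)
}
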
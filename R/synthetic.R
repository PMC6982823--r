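#' Specification for a synthetic extraction curve
#'
#' Describes one synthetic kinetic run: the bed system, the generating BIC
#' parameters, the weighing schedule and the noise model. The defaults
#' emulate the bundled case study's procedure — cumulative extract weighed
#' every 30 minutes over an 8-hour run — with additive Gaussian balance
#' noise on the cumulative mass (SD expressed as a fraction of the
#' extractable load `N x0`, default 1\%).
#'
#' @param system an [extraction_system()].
#' @param params a [bic_parameters()] object.
#' @param sampling_interval weighing interval (s), default 1800.
#' @param duration run length (s), default 8 h.
#' @param noise_sigma noise SD as a fraction of `N x0` (>= 0), default 0.01.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return an object of class `curve_gen_spec`.
#' @export
curve_gen_spec <- function(system, params, sampling_interval = 1800,
                           duration = 8 * 3600, noise_sigma = 0.01,
                           seed = 1) {
  stopifnot(inherits(system, "extraction_system"),
            inherits(params, "bic_parameters"),
            sampling_interval > 0, duration >= sampling_interval,
            noise_sigma >= 0)
  structure(list(system = system, params = params,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_sigma = noise_sigma, seed = seed),
            class = "curve_gen_spec")
}

#' Generate a synthetic extraction curve
#'
#' Evaluates the noise-free model on the weighing grid and adds i.i.d.
#' Gaussian weighing noise to the cumulative masses, clipped at zero.
#' Cumulative values are deliberately not re-monotonised: the noise models
#' independent balance readings of the accumulating extract, so small
#' decreases between successive weighings are legitimate.
#'
#' @param spec a [curve_gen_spec()].
#' @return an [extraction_curve()] with `provenance = "synthetic"`.
#' @export
gen_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_gen_spec"))
  times <- seq(spec$sampling_interval, spec$duration,
               by = spec$sampling_interval)
  clean <- simulate_curve(times, spec$system, spec$params)
  sd_abs <- spec$noise_sigma * spec$system$N * spec$system$x0
  noisy <- if (sd_abs > 0)
    with_seed(spec$seed,
              pmax(clean$masses + stats::rnorm(length(times), 0, sd_abs), 0))
  else clean$masses
  extraction_curve(times, noisy, spec$system, provenance = "synthetic")
}

#' Synthetic kinetic curves for the ten case-study experiments
#'
#' One curve per experiment row, generated from the curve-estimated kinetic
#' parameters under the tabulated bed conditions: 8-hour runs sampled every
#' 30 minutes, noise-free by default. These stand in for the study's
#' unpublished raw kinetic curves; they are synthetic reconstructions, not
#' measurements.
#'
#' @param noise_sigma weighing-noise SD as a fraction of `N x0`.
#' @param seed base RNG seed (experiment `i` uses `seed + i`).
#' @param approach kinetic parameter set, see [lentiscus_kinetics()].
#' @return a named list of ten [extraction_curve()] objects.
#' @export
lentiscus_curves <- function(noise_sigma = 0, seed = 20200103,
                             approach = "fit") {
  params <- lentiscus_kinetics(approach)
  out <- lapply(seq_len(nrow(params)), function(i) {
    pt <- params[i, ]
    spec <- curve_gen_spec(system = lentiscus_system(pt$exp),
                           params = bic_parameters(pt$G, pt$ksa0, pt$kfa0),
                           noise_sigma = noise_sigma, seed = seed + i)
    gen_curve(spec)
  })
  names(out) <- paste0("exp", params$exp)
  out
}

#' Generate a synthetic factorial-design response
#'
#' Evaluates the first-order-with-interactions yield model on a coded
#' design and adds Gaussian run-to-run noise — the generating model of the
#' design-analysis stage.
#'
#' @param coefficients named numeric vector
#'   `c(a0, a1, a2, a3, a12, a13, a23)`.
#' @param design data frame with coded columns `x1`, `x2`, `x3`; defaults to
#'   the bundled coded design.
#' @param noise_sigma response noise SD (% yield).
#' @param seed RNG seed.
#' @return the design with a `yield` column appended.
#' @export
gen_doe <- function(coefficients, design = lentiscus_design_coded(),
                    noise_sigma = 0, seed = 1) {
  stopifnot(length(coefficients) == 7, noise_sigma >= 0)
  want <- c("a0", "a1", "a2", "a3", "a12", "a13", "a23")
  if (!is.null(names(coefficients))) coefficients <- coefficients[want]
  X <- rsm_design_matrix(design)
  mu <- drop(X %*% unname(coefficients))
  y <- if (noise_sigma > 0)
    with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sigma))
  else mu
  out <- design
  out$yield <- y
  out
}
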
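#' Code natural factor settings to the [-1, 1] scale
#'
#' `x = (value - center)/half_range` with the center and half-range taken
#' from the declared (low, high) levels. Values outside the declared range
#' are flagged with a warning but kept (manually controlled factors drift
#' slightly past their nominal levels).
#'
#' @param values numeric vector of natural settings.
#' @param low,high the factor's design levels.
#' @return coded values; `decode_factors()` is the exact inverse.
#' @examples
#' code_factors(c(80, 150, 220), low = 80, high = 220)  # -1, 0, 1
#' @export
code_factors <- function(values, low, high) {
  stopifnot(high > low)
  if (any(values < low | values > high))
    warning("value(s) outside the declared factor range", call. = FALSE)
  (values - (low + high) / 2) / ((high - low) / 2)
}

#' @rdname code_factors
#' @param coded coded values to map back to natural units.
#' @export
decode_factors <- function(coded, low, high) {
  stopifnot(high > low)
  coded * (high - low) / 2 + (low + high) / 2
}

rsm_formula <- stats::as.formula(y ~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3)

rsm_design_matrix <- function(design) {
  stopifnot(all(c("x1", "x2", "x3") %in% names(design)))
  stats::model.matrix(~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3, data = design)
}

#' Fit the first-order-with-interactions response-surface model
#'
#' Ordinary least squares of the yield on the three coded factors and their
#' three two-way interactions:
#' \deqn{Y_D = a_0 + a_1 x_1 + a_2 x_2 + a_3 x_3 + a_{12} x_1 x_2
#'       + a_{13} x_1 x_3 + a_{23} x_2 x_3.}
#' Inference uses the t distribution on `n - 7` residual degrees of freedom;
#' predictive fit is the leave-one-out PRESS statistic,
#' `predicted R^2 = 1 - PRESS/SS_tot`.
#'
#' @param design a data frame with coded columns `x1`, `x2`, `x3` and the
#'   observed response in `yield` (percent).
#' @return an object of class `rsm_fit`: the coefficient table
#'   (`coefficients` data frame with estimates, SE, t, p, stars), `r2`,
#'   `r2_predicted`, `lm` (the underlying [stats::lm] fit) and the design.
#' @export
fit_rsm <- function(design) {
  stopifnot(is.data.frame(design), "yield" %in% names(design))
  if (nrow(design) < 8)
    stop("need at least 8 runs to estimate 7 coefficients", call. = FALSE)
  dat <- data.frame(y = design$yield, design[c("x1", "x2", "x3")])
  fit <- stats::lm(rsm_formula, data = dat)
  if (fit$rank < 7) {
    ali <- stats::alias(fit)$Complete
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(ali), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  ct$stars <- stats::symnum(ct$p, cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                            symbols = c("***", "**", "*", ""), corr = FALSE,
                            legend = FALSE)
  rownames(ct) <- c("a0", "a1", "a2", "a3", "a12", "a13", "a23")
  h <- stats::hatvalues(fit)
  press <- sum((stats::resid(fit) / (1 - h))^2)
  sst <- sum((dat$y - mean(dat$y))^2)
  structure(list(coefficients = ct, r2 = sm$r.squared,
                 r2_predicted = 1 - press / sst, press = press,
                 lm = fit, design = design, n = nrow(design)),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Factorial yield model, %d runs\n", x$n))
  ct <- x$coefficients
  stats::printCoefmat(as.matrix(ct[, c("estimate", "se", "t", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("R^2 = %.4f (%.1f%% of yield variability), predicted R^2 = %.4f\n",
              x$r2, 100 * x$r2, x$r2_predicted))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) print(object)

#' @export
coef.rsm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  unname(stats::predict(object$lm, newdata = newdata))
}

#' @export
residuals.rsm_fit <- function(object, ...) stats::resid(object$lm)

#' @export
plot.rsm_fit <- function(x, ...) {
  graphics::plot(stats::fitted(x$lm), x$design$yield,
                 xlab = "design-model yield (%)",
                 ylab = "observed yield (%)", main = "Observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Reduce the factorial model to its significant terms
#'
#' Keeps the intercept plus every term whose two-sided p-value falls below
#' `alpha`; the retained coefficients are those of the full fit. On the
#' bundled leaf-extraction design this retains only the intercept and the
#' pressure effect.
#'
#' @param fit an [fit_rsm()] result.
#' @param alpha significance level (default 0.05).
#' @return a list with `terms` (retained non-intercept names),
#'   `coefficients` (named, incl. intercept) and a formatted `equation`
#'   string.
#' @export
reduce_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"), alpha > 0, alpha <= 1)
  ct <- fit$coefficients
  keep <- rownames(ct)[ct$p < alpha | rownames(ct) == "a0"]
  coefs <- stats::setNames(ct[keep, "estimate"], keep)
  terms <- setdiff(keep, "a0")
  labels <- c(a1 = "x1", a2 = "x2", a3 = "x3",
              a12 = "x1*x2", a13 = "x1*x3", a23 = "x2*x3")
  eq <- paste0("YD = ", sprintf("%.3f", coefs[["a0"]]))
  for (tm in terms)
    eq <- paste0(eq, sprintf(" %s %.3f*%s", ifelse(coefs[[tm]] < 0, "-", "+"),
                             abs(coefs[[tm]]), labels[[tm]]))
  list(terms = terms, coefficients = coefs, equation = eq, alpha = alpha)
}

#' Pairwise correlations among the model-term columns of a design
#'
#' The correlation structure of the six non-intercept model columns
#' (`x1, x2, x3, x1x2, x1x3, x2x3`) of the design matrix: a 6x6 symmetric
#' matrix with unit diagonal, depending on the design only, never on the
#' observed response. Correlated columns inflate the confidence intervals of
#' the corresponding coefficient estimates; for an orthogonal two-level full
#' factorial the matrix is the identity.
#'
#' @param design data frame with coded columns `x1`, `x2`, `x3`.
#' @return a 6x6 correlation matrix with rows/columns
#'   `a1, a2, a3, a12, a13, a23`.
#' @export
coef_correlations <- function(design) {
  X <- rsm_design_matrix(design)[, -1, drop = FALSE]
  if (qr(cbind(1, X))$rank < 7)
    stop("rank-deficient design", call. = FALSE)
  C <- stats::cor(X)
  dimnames(C) <- rep(list(c("a1", "a2", "a3", "a12", "a13", "a23")), 2)
  C
}

#' Fraction of coefficient-pair correlations inside a magnitude band
#'
#' Over the 15 distinct off-diagonal pairs of a 6x6 correlation matrix,
#' the percentage (nearest integer) whose absolute correlation lies in the
#' closed band.
#'
#' @param mat a symmetric correlation matrix (unit diagonal).
#' @param band closed interval of absolute correlation, default
#'   `c(0.2, 0.4)`.
#' @return percentage (0--100, nearest integer).
#' @export
correlation_band_percent <- function(mat, band = c(0.2, 0.4)) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            max(abs(mat - t(mat))) < 1e-8, all(abs(diag(mat) - 1) < 1e-8))
  r <- abs(mat[upper.tri(mat)])
  round(100 * mean(r >= band[1] & r <= band[2]))
}

#' D-optimal subset selection by Fedorov exchange
#'
#' Selects `k` candidate runs maximising `det(X'X)` of the model matrix
#' (intercept included) by iterative single-point exchange from a random
#' full-rank start. The determinant never decreases across iterations; the
#' algorithm stops when no exchange improves it (or after `max_passes`).
#'
#' @param candidates data frame of candidate runs with coded columns
#'   `x1`, `x2`, `x3` (or the columns named in `formula`).
#' @param k subset size, at least the number of model parameters.
#' @param formula model formula (right-hand side) applied to the candidates;
#'   defaults to the first-order-with-interactions yield model.
#' @param seed RNG seed for the random start.
#' @param max_passes maximum exchange sweeps.
#' @return a list with `indices` (selected candidate rows), `logdet`,
#'   `logdet_trace` (one value per accepted exchange, non-decreasing) and
#'   `passes`.
#' @export
d_optimal_select <- function(candidates, k,
                             formula = ~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3,
                             seed = 20200103, max_passes = 1000) {
  X <- stats::model.matrix(formula, data = candidates)
  p <- ncol(X)
  n <- nrow(X)
  if (k < p) stop("'k' must be at least the number of model parameters",
                  call. = FALSE)
  if (k > n) stop("'k' exceeds the number of candidates", call. = FALSE)
  if (qr(X)$rank < p) stop("candidate set is rank deficient", call. = FALSE)

  logdet <- function(idx) {
    d <- determinant(crossprod(X[idx, , drop = FALSE]), logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }
  sel <- with_seed(seed, {
    repeat {
      s <- sample.int(n, k)
      if (logdet(s) > -Inf) break
    }
    s
  })
  cur <- logdet(sel)
  trace <- cur
  passes <- 0L
  repeat {
    passes <- passes + 1L
    improved <- FALSE
    for (i in seq_len(k)) {
      outside <- setdiff(seq_len(n), sel)
      best_j <- NA_integer_
      best_ld <- cur
      for (j in outside) {
        cand <- sel
        cand[i] <- j
        ld <- logdet(cand)
        if (ld > best_ld + 1e-12) {
          best_ld <- ld
          best_j <- j
        }
      }
      if (!is.na(best_j)) {
        sel[i] <- best_j
        cur <- best_ld
        trace <- c(trace, cur)
        improved <- TRUE
      }
    }
    if (!improved || passes >= max_passes) break
  }
  list(indices = sort(sel), logdet = cur, logdet_trace = trace,
       passes = passes)
}

#' Predicted-yield grid over a coded factor pair
#'
#' Evaluates the fitted factorial model over a regular coded grid of one
#' factor pair, holding the third factor fixed — the numerical analogue of a
#' response-surface plot.
#'
#' @param fit an [fit_rsm()] result.
#' @param pair character vector of two factor names, e.g. `c("x1","x2")`.
#' @param fixed value of the remaining factor (coded), default 0.
#' @param n grid resolution per axis.
#' @return a data frame with the two grid coordinates and `yield`.
#' @export
surface_grid <- function(fit, pair = c("x1", "x2"), fixed = 0, n = 21) {
  stopifnot(inherits(fit, "rsm_fit"), length(pair) == 2,
            all(pair %in% c("x1", "x2", "x3")))
  other <- setdiff(c("x1", "x2", "x3"), pair)
  g <- expand.grid(a = seq(-1, 1, length.out = n),
                   b = seq(-1, 1, length.out = n))
  nd <- stats::setNames(data.frame(g$a, g$b, fixed), c(pair, other))
  out <- nd[pair]
  out$yield <- predict(fit, nd)
  out
}
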
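#' SigFit: calibrated wide-pulse signal model
#'
#' In the wide-pulse limit the apparent diffusion coefficient of spins
#' restricted in a cell of size L is approximately
#' ADC = c0 L^4 / (D0 delta (Delta - delta/3))
#'     - c1 L^6 / (D0^2 delta^2 (Delta - delta/3)),
#' with geometry constants c0, c1 calibrated by linear least squares (through
#' the origin) on simulated noise-free intracellular ADCs. The signal model is
#' s = s0 exp(-b ADC), fitted jointly for (s0, D0, L) per decay. Note the
#' signal is mono-exponential in b, so a single decay constrains only
#' (s0, ADC): the joint fit returns a point on the ADC(D0, L) = const ridge,
#' which the multi-start explores; the fixed-D0 variant pins D0 and makes L
#' identifiable.
#'
#' @name sigfit
NULL

#' Wide-pulse apparent diffusion coefficient
#'
#' @param D0 Intrinsic diffusivity (um^2/ms, > 0).
#' @param L Cell size (um).
#' @param delta,Delta PGSE timings (ms), with Delta - delta/3 > 0.
#' @param c0,c1 Geometry constants.
#' @return ADC in um^2/ms (can be negative where the model leaves its
#'   validity region; see [sigfit_signal()]).
#' @export
adc_model <- function(D0, L, delta, Delta, c0, c1) {
  td <- Delta - delta / 3
  if (any(td <= 0)) stop("Delta - delta/3 must be positive")
  if (any(D0 <= 0)) stop("D0 must be positive")
  c0 * L^4 / (D0 * delta * td) - c1 * L^6 / (D0^2 * delta^2 * td)
}

#' Model signal decay
#'
#' s = s0 exp(-b ADC); a negative model ADC is clipped at a small positive
#' floor for signal evaluation (flagging is the fitter's job).
#'
#' @param b b-values (s/mm^2).
#' @param s0 Non-DW signal.
#' @param D0,L,delta,Delta,c0,c1 As in [adc_model()].
#' @return Signal vector.
#' @export
sigfit_signal <- function(b, s0, D0, L, delta, Delta, c0, c1) {
  adc <- max(adc_model(D0, L, delta, Delta, c0, c1), 1e-6)
  s0 * exp(-b_to_internal(b) * adc)
}

#' Calibrate the geometry constants c0, c1
#'
#' Linear least squares through the origin of simulated ADCs on the two model
#' regressors L^4/(D0 delta (Delta - delta/3)) and
#' -L^6/(D0^2 delta^2 (Delta - delta/3)).
#'
#' @param adc Simulated apparent diffusion coefficients (um^2/ms).
#' @param D0,L,delta,Delta Configuration of each sample (recycled to common
#'   length).
#' @param weights Optional per-row weights. `"normalized"` gives each
#'   configuration equal voice by weighting with 1/x1 -- equivalent to
#'   regressing the normalized ADC, adc * D0 * delta * (Delta - delta/3) /
#'   L^4, linearly on u = L^2 / (D0 delta). The default (`NULL`) is plain
#'   unweighted least squares, where configurations with the largest L^4
#'   regressors dominate.
#' @param calibration Optional descriptor of the calibration set, stored on
#'   the model.
#' @return A `sigfit_model` with `c0`, `c1`.
#' @export
calibrate_constants <- function(adc, D0, L, delta, Delta, weights = NULL,
                                calibration = NULL) {
  td <- Delta - delta / 3
  x1 <- L^4 / (D0 * delta * td)
  x2 <- -L^6 / (D0^2 * delta^2 * td)
  if (is.character(weights) && identical(weights, "normalized"))
    weights <- 1 / x1
  if (is.null(weights)) weights <- rep(1, length(x1))
  X <- cbind(x1 * weights, x2 * weights)
  if (nrow(X) < 2) stop("calibrate_constants: need at least 2 rows")
  qrX <- qr(X)
  if (qrX$rank < 2) stop("calibrate_constants: rank-deficient regressors")
  cf <- qr.coef(qrX, adc * weights)
  structure(list(c0 = unname(cf[1]), c1 = unname(cf[2]),
                 calibration = calibration),
            class = "sigfit_model")
}

#' @export
print.sigfit_model <- function(x, ...) {
  cat(sprintf("SigFit constants: c0 = %.4g, c1 = %.4g\n", x$c0, x$c1))
  invisible(x)
}

#' Fit the wide-pulse signal model to a decay
#'
#' Bounded nonlinear least squares on the linear-domain signal for
#' (s0, D0, L) jointly, with a multi-start over a coarse (D0, L) lattice to
#' cover the D0-L degeneracy ridge; residual ties (within a relative 1e-6)
#' are broken toward smaller L. With `fixed_D0` given, only (s0, L) are
#' fitted.
#'
#' @param b b-values (s/mm^2), at least 3 (2 with `fixed_D0`).
#' @param s Signals.
#' @param delta,Delta PGSE timings (ms).
#' @param model A `sigfit_model` (calibrated constants).
#' @param fixed_D0 Optional pinned intrinsic diffusivity (um^2/ms).
#' @param box Fit box: list with `s0`, `D0`, `L` ranges.
#' @param starts Multi-start lattice: list with `D0`, `L` vectors.
#' @return A `sigfit_result`: `s0`, `D0_hat`, `L_hat`, `fixed_D0`,
#'   `residual_norm`, `converged`, `adc_hat`.
#' @export
fit_signal <- function(b, s, delta, Delta, model, fixed_D0 = NULL,
                       box = list(s0 = c(0, 1), D0 = c(0.1, 3), L = c(5, 80)),
                       starts = list(D0 = c(0.3, 0.7, 1.1, 1.5, 1.9, 2.3),
                                     L = c(10, 20, 30, 40, 50, 60))) {
  need <- if (is.null(fixed_D0)) 3 else 2
  if (length(unique(b)) < need) stop("fit_signal: not enough b-values")
  bi <- b_to_internal(b)
  fixed <- !is.null(fixed_D0)

  resid_fn <- function(p) {
    d0 <- if (fixed) fixed_D0 else p[2]
    l <- if (fixed) p[2] else p[3]
    adc <- max(adc_model(d0, l, delta, Delta, model$c0, model$c1), 1e-6)
    s - p[1] * exp(-bi * adc)
  }
  run_one <- function(par, lower, upper) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, rss = sum(resid_fn(fit$par)^2),
         converged = fit$info %in% 1:4)
  }

  s0_start <- min(max(max(s), 1e-3), box$s0[2])
  cands <- list()
  if (fixed) {
    for (l0 in starts$L)
      cands[[length(cands) + 1L]] <-
        run_one(c(s0_start, l0), c(1e-10, box$L[1]), c(box$s0[2], box$L[2]))
  } else {
    for (d0 in starts$D0) for (l0 in starts$L)
      cands[[length(cands) + 1L]] <-
        run_one(c(s0_start, d0, l0),
                c(1e-10, box$D0[1], box$L[1]),
                c(box$s0[2], box$D0[2], box$L[2]))
  }
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) stop("fit_signal: all starts failed")
  rss <- vapply(cands, `[[`, numeric(1), "rss")
  best_rss <- min(rss)
  tied <- which(rss <= best_rss * (1 + 1e-6) + 1e-30)
  lhat <- vapply(cands[tied], function(cc) cc$par[length(cc$par)], numeric(1))
  pick <- cands[[tied[which.min(lhat)]]]

  d0_hat <- if (fixed) fixed_D0 else pick$par[2]
  l_hat <- pick$par[length(pick$par)]
  structure(list(s0 = pick$par[1], D0_hat = d0_hat, L_hat = l_hat,
                 fixed_D0 = if (fixed) fixed_D0 else NA_real_,
                 residual_norm = sqrt(pick$rss),
                 converged = pick$converged,
                 adc_hat = max(adc_model(d0_hat, l_hat, delta, Delta,
                                         model$c0, model$c1), 1e-6)),
            class = "sigfit_result")
}

#' @export
print.sigfit_result <- function(x, ...) {
  cat(sprintf("SigFit: s0 = %.4f, D0 = %.3f, L = %.2f um (ADC %.4f, resid %.3g)\n",
              x$s0, x$D0_hat, x$L_hat, x$adc_hat, x$residual_norm))
  invisible(x)
}
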
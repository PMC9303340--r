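#' Cumulant-expansion (DKI) fitting
#'
#' Second-order cumulant expansion of the log signal,
#' ln s = ln s0 - b D + (1/6) K (b D)^2, fitted by bounded nonlinear least
#' squares on the log signal, initialized from an ordinary least-squares fit
#' of ln s on (1, b, b^2). Bounds: 0 <= s0 <= 1, 0 <= D <= 2.4 um^2/ms,
#' -5 <= K <= 10.
#'
#' @name cumulants
NULL

#' Fit apparent diffusion and kurtosis coefficients
#'
#' @param b b-values in s/mm^2 (>= 3 distinct values).
#' @param s Signals (same length); values <= `clip` are clipped before the
#'   log with a flag.
#' @param bounds List with `s0`, `D`, `K` two-element ranges.
#' @param clip Positive floor applied to signals (default 1e-6).
#' @param log_domain Fit the objective on the log signal (default TRUE, the
#'   form the expansion is written in); `FALSE` fits the linear-domain
#'   signal instead.
#' @return A `dki_fit`: `s0`, `D` (um^2/ms), `K`, `residual_norm`,
#'   `converged`, `clipped`, `at_bound`.
#' @examples
#' b <- make_bvalues(100, 2000, 7)
#' s <- 0.95 * exp(-b * 1e-3 * 0.8 + (1.2 / 6) * (b * 1e-3 * 0.8)^2)
#' fit_dki(b, s)
#' @export
fit_dki <- function(b, s,
                    bounds = list(s0 = c(0, 1), D = c(0, 2.4), K = c(-5, 10)),
                    clip = 1e-6, log_domain = TRUE) {
  if (length(unique(b)) < 3) stop("fit_dki: need at least 3 distinct b-values")
  if (length(b) != length(s)) stop("fit_dki: length mismatch")
  clipped <- any(s <= clip)
  if (clipped) warning("fit_dki: non-positive signals clipped before log")
  y <- log(pmax(s, clip))
  bi <- b_to_internal(b)

  if (max(y) - min(y) < 1e-12) {
    # flat decay: degenerate, return the trivial fit
    s0 <- min(max(exp(y[1]), bounds$s0[1]), bounds$s0[2])
    return(structure(list(s0 = s0, D = 0, K = 0, residual_norm = 0,
                          converged = FALSE, clipped = clipped,
                          at_bound = c(D = TRUE), degenerate = TRUE),
                     class = "dki_fit"))
  }

  # linear initialization: ln s ~ c0 + c1 b + c2 b^2
  X <- cbind(1, bi, bi^2)
  cf <- qr.coef(qr(X), y)
  D0 <- min(max(-cf[2], bounds$D[1] + 1e-9), bounds$D[2])
  K0 <- if (D0 > 1e-9) 6 * cf[3] / D0^2 else 0
  K0 <- min(max(K0, bounds$K[1]), bounds$K[2])
  s00 <- min(max(exp(cf[1]), 1e-8), bounds$s0[2])

  if (log_domain) {
    resid_fn <- function(p) {
      y - (log(p[1]) - bi * p[2] + p[3] * (bi * p[2])^2 / 6)
    }
    jac_fn <- function(p) {
      -cbind(1 / p[1],
             -bi + p[3] * bi^2 * p[2] / 3,
             (bi * p[2])^2 / 6)
    }
  } else {
    resid_fn <- function(p) {
      s - p[1] * exp(-bi * p[2] + p[3] * (bi * p[2])^2 / 6)
    }
    jac_fn <- function(p) {
      e <- exp(-bi * p[2] + p[3] * (bi * p[2])^2 / 6)
      -cbind(e,
             p[1] * e * (-bi + p[3] * bi^2 * p[2] / 3),
             p[1] * e * (bi * p[2])^2 / 6)
    }
  }
  fit <- minpack.lm::nls.lm(
    par = c(s00, D0, K0), fn = resid_fn, jac = jac_fn,
    lower = c(max(bounds$s0[1], 1e-10), bounds$D[1], bounds$K[1]),
    upper = c(bounds$s0[2], bounds$D[2], bounds$K[2]),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200))
  p <- fit$par
  at_bound <- c(s0 = p[1] <= bounds$s0[1] + 1e-9 || p[1] >= bounds$s0[2] - 1e-9,
                D = p[2] <= bounds$D[1] + 1e-9 || p[2] >= bounds$D[2] - 1e-9,
                K = p[3] <= bounds$K[1] + 1e-9 || p[3] >= bounds$K[2] - 1e-9)
  structure(list(s0 = p[1], D = p[2], K = p[3],
                 residual_norm = sqrt(sum(resid_fn(p)^2)),
                 converged = fit$info %in% 1:4, clipped = clipped,
                 at_bound = at_bound, degenerate = FALSE),
            class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  cat(sprintf("DKI fit: s0 = %.4f, D = %.4f um^2/ms, K = %.4f (resid %.3g%s)\n",
              x$s0, x$D, x$K, x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Mono-exponential ADC fit
#'
#' Log-linear least squares of ln s on b; used to extract apparent diffusion
#' coefficients for the wide-pulse calibration.
#'
#' @param b b-values (s/mm^2).
#' @param s Signals.
#' @return List with `s0` and `adc` (um^2/ms).
#' @export
fit_adc <- function(b, s) {
  y <- log(pmax(s, 1e-12))
  bi <- b_to_internal(b)
  cf <- qr.coef(qr(cbind(1, bi)), y)
  list(s0 = unname(exp(cf[1])), adc = unname(-cf[2]))
}
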
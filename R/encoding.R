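#' PGSE diffusion encoding
#'
#' Single diffusion encoding with two rectangular gradient lobes of duration
#' delta separated by Delta; for rectangular lobes
#' b = gamma^2 G^2 delta^2 (Delta - delta/3). Waveforms are represented as the
#' *effective* gradient (second lobe negated by the refocusing pulse), so the
#' zeroth moment vanishes and static spins rephase perfectly.
#'
#' @name encoding
NULL

#' Uniformly spaced b-value shells
#'
#' @param bmin,bmax Range endpoints in s/mm^2 (both acquired).
#' @param n Number of shells (>= 2).
#' @return Numeric vector of `n` linearly spaced b-values.
#' @examples
#' make_bvalues(100, 1000, 7)  # spacing 150
#' @export
make_bvalues <- function(bmin, bmax, n) {
  if (!(bmin > 0 && bmax > bmin)) stop("require 0 < bmin < bmax")
  if (n < 2) stop("n must be >= 2")
  seq(bmin, bmax, length.out = n)
}

#' Construct a PGSE protocol
#'
#' @param delta Gradient duration (ms).
#' @param Delta Gradient separation (ms).
#' @param bmax Maximum b-value (s/mm^2).
#' @param bmin Minimum nonzero b-value (s/mm^2), default 100 (suppresses most
#'   perfusion signal).
#' @param n_b Number of nonzero b-values (default 7).
#' @param snr Signal-to-noise ratio at b = 0 (`Inf` for noise-free).
#' @param directions Matrix of unit gradient directions, one per row
#'   (default the three laboratory axes).
#' @param Ts Total simulated time budget the waveform must fit (ms).
#' @return A `pgse_protocol` list.
#' @export
pgse_protocol <- function(delta, Delta, bmax, bmin = 100, n_b = 7, snr = Inf,
                          directions = diag(3), Ts = 140) {
  if (delta <= 0) stop("delta must be > 0")
  if (Delta < delta) stop("Delta must be >= delta")
  if (delta + Delta > Ts) stop("waveform exceeds the simulated time Ts")
  b <- make_bvalues(bmin, bmax, n_b)
  structure(list(delta = delta, Delta = Delta, b_values = b, snr = snr,
                 directions = directions, gamma = GAMMA_INTERNAL),
            class = "pgse_protocol")
}

#' The five gradient timings of the simulation study
#'
#' delta/Delta pairs (ms): 10/50, 20/25, 20/50, 20/75, 40/50.
#'
#' @return Data frame with columns `delta`, `Delta`.
#' @export
study_timings <- function() {
  data.frame(delta = c(10, 20, 20, 20, 40), Delta = c(50, 25, 50, 75, 50))
}

#' Gradient amplitude for a target b-value
#'
#' Inverts b = gamma^2 G^2 delta^2 (Delta - delta/3).
#'
#' @param b b-value in s/mm^2 (>= 0).
#' @param delta,Delta Timings in ms.
#' @return Amplitude in internal units (mT/um).
#' @export
gradient_amplitude <- function(b, delta, Delta) {
  td <- Delta - delta / 3
  if (td <= 0) stop("Delta - delta/3 must be positive")
  if (any(b < 0)) stop("b must be non-negative")
  sqrt(b_to_internal(b) / (GAMMA_INTERNAL^2 * delta^2 * td))
}

#' Lobe windows on the trajectory sample grid
#'
#' Sample j (position after j steps) carries effective gradient +G for
#' j in [0, n1) and -G for j in [m, m + n1), with n1 = round(delta/dt) and
#' m = round(Delta/dt); equal lobe lengths make the zeroth moment vanish
#' exactly.
#'
#' @param delta,Delta Timings (ms).
#' @param dt Sample spacing (ms).
#' @return Integer vector `c(n1, m)`.
#' @export
lobe_samples <- function(delta, Delta, dt) {
  n1 <- as.integer(round(delta / dt))
  m <- as.integer(round(Delta / dt))
  if (n1 < 1) stop("delta shorter than one sample")
  c(n1 = n1, m = m)
}

#' Sampled effective gradient waveform
#'
#' @param delta,Delta Timings (ms).
#' @param b Target b-value (s/mm^2).
#' @param direction Unit 3-vector.
#' @param dt Sample spacing (ms).
#' @param n_steps Number of walk steps (waveform has `n_steps + 1` samples).
#' @return `(n_steps + 1) x 3` matrix of effective gradient vectors (mT/um).
#' @export
effective_waveform <- function(delta, Delta, b, direction, dt, n_steps) {
  lo <- lobe_samples(delta, Delta, dt)
  if (lo["m"] + lo["n1"] > n_steps)
    stop("waveform exceeds the simulated time window")
  g <- gradient_amplitude(b, delta, Delta)
  w <- numeric(n_steps + 1)
  w[seq_len(lo["n1"])] <- g                         # samples 0 .. n1-1
  w[lo["m"] + seq_len(lo["n1"])] <- -g              # samples m .. m+n1-1
  outer(w, as.numeric(direction))
}

#' Read a PGSE protocol from a YAML/JSON config
#'
#' Keys: `delta`, `Delta`, `bmin`, `bmax`, `n_b`, `snr` (`.inf` for
#' noise-free), optional `directions` (list of unit 3-vectors).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `pgse_protocol`.
#' @export
protocol_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  dirs <- if (is.null(cfg$directions)) diag(3)
          else do.call(rbind, lapply(cfg$directions, as.numeric))
  pgse_protocol(delta = cfg$delta, Delta = cfg$Delta, bmax = cfg$bmax,
                bmin = cfg$bmin %||% 100, n_b = cfg$n_b %||% 7,
                snr = if (is.null(cfg$snr)) Inf else cfg$snr,
                directions = dirs)
}

#' Numerical b-value of a sampled waveform
#'
#' b = gamma^2 * sum_j q_j^2 * dt with q_j the left-Riemann integral of the
#' effective gradient; cross-checks the analytic formula.
#'
#' @param waveform `(T+1) x 3` effective gradient samples.
#' @param dt Sample spacing (ms).
#' @return b in s/mm^2.
#' @export
numeric_bvalue <- function(waveform, dt) {
  q <- apply(waveform, 2, function(g) cumsum(c(0, g[-length(g)])) * dt)
  GAMMA_INTERNAL^2 * sum(q^2) * dt / 1e-3
}
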
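#' Voxel-level signal synthesis
#'
#' Per-spin phase accrual along simulated trajectories, volume-weighted
#' pooling over the Omega neighborhood and shape ensemble, three-direction
#' averaging, IVIM (perfusion) contamination and Rician noise.
#'
#' @name synthesis
NULL

#' Phase-accrual signal from recorded trajectories
#'
#' Per-spin phase phi_n = gamma * dt * sum_t G(t)' r_n(t) (left-Riemann sum on
#' the trajectory grid); the signal is the magnitude of the mean phasor
#' |mean_n exp(-i phi_n)|.
#'
#' @param traj A `trajectories` object with recorded positions.
#' @param waveform `(n_steps + 1) x 3` effective gradient samples (mT/um).
#' @param return_phases Also return the per-spin phases (for Monte Carlo
#'   error estimation).
#' @return Signal magnitude, or a list `(signal, phases)`.
#' @export
phase_signal <- function(traj, waveform, return_phases = FALSE) {
  if (is.null(traj$positions)) stop("phase_signal: trajectories were not recorded")
  d <- dim(traj$positions)
  if (nrow(waveform) != d[2])
    stop("phase_signal: waveform not sampled on the trajectory time grid")
  m <- matrix(traj$positions, nrow = d[1])      # N x (T+1 * 3), (j, axis) order
  phases <- as.numeric(GAMMA_INTERNAL * traj$dt * (m %*% as.numeric(waveform)))
  s <- Mod(mean(exp(-1i * phases)))
  if (return_phases) list(signal = s, phases = phases) else s
}

#' Signal from lobe accumulators
#'
#' Fast path used by grid runs: with A the per-spin lobe position sums for one
#' PGSE timing (see [walk()]), the phase is gamma * G * dt * (A g) and the
#' signal |mean exp(-i phi)| needs no stored trajectory.
#'
#' @param A N x 3 matrix of lobe accumulators for one timing.
#' @param G Gradient amplitude (mT/um).
#' @param dt Sample spacing (ms).
#' @param direction Unit 3-vector.
#' @return Signal magnitude.
#' @export
lobe_signal <- function(A, G, dt, direction) {
  phi <- GAMMA_INTERNAL * G * dt * as.numeric(A %*% as.numeric(direction))
  Mod(mean(exp(-1i * phi)))
}

#' Volume-weighted pooled signal
#'
#' Weighted mean of per-cell signals with weights L^3 (nominal cell size of
#' each ensemble member), normalized to sum 1: cells are weighted by the water
#' volume they contribute to the voxel.
#'
#' @param signals Numeric vector of per-cell signals.
#' @param L Nominal sizes (um) of the corresponding cells.
#' @return Pooled signal.
#' @export
pooled_signal <- function(signals, L) {
  if (length(signals) != length(L)) stop("pooled_signal: length mismatch")
  if (anyNA(signals)) stop("pooled_signal: missing ensemble member signal")
  w <- L^3
  sum(w * signals) / sum(w)
}

#' Average signals over gradient directions
#'
#' @param signals Per-direction signal values.
#' @return Arithmetic mean.
#' @export
direction_average <- function(signals) {
  if (length(signals) < 1) stop("direction_average: no directions")
  mean(signals)
}

#' Draw IVIM contamination parameters
#'
#' Perfusion fraction f and pseudo-diffusivity Dv drawn independently and
#' uniformly on their ranges.
#'
#' @param n Number of draws.
#' @param f_range Range of f (default 0.05..0.50).
#' @param Dv_range Range of Dv in um^2/ms (default 15..60).
#' @param seed Integer seed.
#' @return Data frame with columns `f`, `Dv`.
#' @export
draw_ivim <- function(n, f_range = c(0.05, 0.50), Dv_range = c(15, 60),
                      seed = 1L) {
  with_seed(seed, data.frame(f = runif(n, f_range[1], f_range[2]),
                             Dv = runif(n, Dv_range[1], Dv_range[2])))
}

#' Add IVIM (perfusion) contamination
#'
#' s = f exp(-b Dv) + (1 - f) s_intra, with b converted to ms/um^2.
#'
#' @param s_intra Intracellular signal(s).
#' @param b b-value(s) in s/mm^2.
#' @param f Perfusion fraction in `[0, 1]`.
#' @param Dv Pseudo-diffusivity (um^2/ms).
#' @return Contaminated signal.
#' @export
add_ivim <- function(s_intra, b, f, Dv) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  f * exp(-b_to_internal(b) * Dv) + (1 - f) * s_intra
}

#' Add Rician noise
#'
#' Magnitude-reconstruction noise: sqrt((s + e1)^2 + e2^2) with e1, e2 ~
#' N(0, sigma^2) and sigma = 1/SNR on the s(b = 0) = 1 scale. `snr = Inf`
#' returns the input unchanged.
#'
#' @param s Noise-free signal(s).
#' @param snr SNR at b = 0 (> 0 or Inf).
#' @param seed Integer seed (optional; when NULL the current RNG stream is
#'   used).
#' @return Noisy signal(s).
#' @export
add_rician <- function(s, snr, seed = NULL) {
  if (snr <= 0) stop("snr must be positive")
  if (is.infinite(snr)) return(s)
  sigma <- 1 / snr
  draw <- function() {
    e1 <- rnorm(length(s), sd = sigma)
    e2 <- rnorm(length(s), sd = sigma)
    sqrt((s + e1)^2 + e2^2)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Narrow-pulse signal in a 1-D reflecting segment
#'
#' Closed-form diffusion propagator solution for spins uniformly filling a
#' segment of width `a` with reflecting ends, probed by ideal narrow gradient
#' pulses of wave-number q and separation t: the independent oracle for the
#' mesh-bounded simulator in box geometry (a box factorizes into a product of
#' per-axis segments).
#'
#' @param q Wave-number gamma * G * delta (rad/um).
#' @param t Diffusion time (ms).
#' @param a Segment width (um).
#' @param D0 Diffusivity (um^2/ms).
#' @param n_terms Number of eigenmodes (default 100).
#' @return Signal in `[0, 1]`.
#' @export
narrow_pulse_segment <- function(q, t, a, D0, n_terms = 100) {
  qa <- q * a
  if (abs(qa) < 1e-12) return(1)
  s <- 2 * (1 - cos(qa)) / qa^2
  for (n in seq_len(n_terms)) {
    den <- (qa^2 - (n * pi)^2)^2
    if (den < 1e-12) den <- 1e-12  # removable singularity guard
    s <- s + 4 * qa^2 * exp(-n^2 * pi^2 * D0 * t / a^2) *
      (1 - (-1)^n * cos(qa)) / den
  }
  s
}
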
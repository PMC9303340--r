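#' Intracellular random walks
#'
#' Spins take fixed-length steps of length sqrt(6 D0 dt) in directions drawn
#' uniformly on the sphere; a step crossing the cell wall is specularly
#' reflected about the intersected face plane, recursively, until the residual
#' sub-step lies inside (impermeable, elastic walls). Positions are recorded at
#' every step.
#'
#' @name montecarlo
NULL

#' Walk configuration
#'
#' @param D0 Intrinsic diffusivity (um^2/ms).
#' @param N Spins per cell (default 1000).
#' @param Ts Total simulated time (ms, default 140).
#' @param n_steps Number of steps (default 3000); `dt = Ts / n_steps`.
#' @param seed Integer seed.
#' @param max_reflect Reflection recursion bound per step (default 20); a spin
#'   exceeding it is clamped at its last valid interior point and counted.
#' @return A `walk_config` list.
#' @export
walk_config <- function(D0, N = 1000L, Ts = 140, n_steps = 3000L, seed = 1L,
                        max_reflect = 20L) {
  stopifnot(D0 >= 0, N >= 1, Ts > 0, n_steps >= 1)
  structure(list(D0 = D0, N = as.integer(N), Ts = Ts,
                 n_steps = as.integer(n_steps), dt = Ts / n_steps,
                 seed = as.integer(seed), max_reflect = as.integer(max_reflect)),
            class = "walk_config")
}

#' Seed spins uniformly inside a cell
#'
#' Rejection sampling in the bounding box with the containment test; fails if
#' the acceptance rate drops below 1% (degenerate mesh).
#'
#' @param mesh A `tri_mesh`.
#' @param N Number of spins.
#' @param seed Integer seed.
#' @return N x 3 matrix of positions (um).
#' @export
seed_spins <- function(mesh, N, seed = 1L) {
  with_seed(seed,
            cpp_seed_spins(mesh$vertices,
                           matrix(as.integer(mesh$faces), ncol = 3),
                           as.integer(N)))
}

#' Simulate restricted random walks in a cell
#'
#' @param mesh A `tri_mesh`.
#' @param cfg A [walk_config()].
#' @param record Keep the full `(N, n_steps + 1, 3)` position array (default
#'   TRUE). With `record = FALSE` only the PGSE lobe accumulators are kept,
#'   which is what grid runs need.
#' @param timings Data frame with columns `delta`, `Delta` (ms): PGSE timings
#'   for which per-spin lobe position sums are accumulated on the fly.
#' @return A `trajectories` object: `positions` (or NULL), `A` (N x 3 x
#'   n_timings lobe accumulators), `dt`, `D0`, `clamped`, `cell` metadata.
#' @export
walk <- function(mesh, cfg, record = TRUE, timings = NULL) {
  stopifnot(inherits(cfg, "walk_config"))
  if (is.null(timings)) timings <- data.frame(delta = numeric(0), Delta = numeric(0))
  lobes <- matrix(0L, nrow = nrow(timings), ncol = 2)
  if (nrow(timings) > 0) {
    for (k in seq_len(nrow(timings))) {
      lo <- lobe_samples(timings$delta[k], timings$Delta[k], cfg$dt)
      if (lo["m"] + lo["n1"] > cfg$n_steps)
        stop("PGSE timing exceeds the simulated window Ts")
      lobes[k, ] <- lo
    }
  }
  step_len <- sqrt(6 * cfg$D0 * cfg$dt)
  res <- with_seed(cfg$seed, {
    start <- cpp_seed_spins(mesh$vertices,
                            matrix(as.integer(mesh$faces), ncol = 3), cfg$N)
    out <- cpp_walk(mesh$vertices, matrix(as.integer(mesh$faces), ncol = 3),
                    start, cfg$n_steps, step_len, lobes, record,
                    cfg$max_reflect)
    out$start <- start
    out
  })
  structure(list(positions = res$positions, A = res$A, start = res$start,
                 dt = cfg$dt, D0 = cfg$D0, n_steps = cfg$n_steps,
                 clamped = res$clamped, timings = timings,
                 cell = list(L_nominal = mesh$L_nominal,
                             base_sides = mesh$base_sides,
                             shape_id = mesh$shape_id)),
            class = "trajectories")
}

#' Mean squared displacement of simulated trajectories
#'
#' @param traj A `trajectories` object with recorded positions.
#' @param times Sample indices (default all).
#' @return Data frame with `t` (ms) and `msd` (um^2).
#' @export
msd <- function(traj, times = NULL) {
  if (is.null(traj$positions)) stop("msd: trajectories were not recorded")
  d <- dim(traj$positions)
  if (is.null(times)) times <- seq_len(d[2])
  disp2 <- vapply(times, function(j) {
    dx <- traj$positions[, j, ] - traj$positions[, 1, ]
    mean(rowSums(dx^2))
  }, numeric(1))
  data.frame(t = (times - 1) * traj$dt, msd = disp2)
}
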
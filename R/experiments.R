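#' Grid experiments: simulate, synthesize, fit, map, classify
#'
#' End-to-end orchestration of the in-silico study: random walks for every
#' (D0, L, shape) on the microstructure grid, PGSE signal synthesis for all
#' protocol contexts (timing x bmax), Omega pooling with L^3 volume weights,
#' three-direction averaging, IVIM contamination, Rician noise, and cumulant
#' fitting. Fully deterministic given the master seed, with per-task child
#' seeds derived by a counter scheme.
#'
#' @name experiments
NULL

#' Experiment configuration
#'
#' Presets: `smoke` (minutes; tiny 5 x 5 grid, 1 centre), `desk` (thinned
#' grid -- every 2nd lattice point in both axes -- 200 spins, 6 shapes,
#' 1500 steps; runs on one CPU in minutes-to-tens-of-minutes), `full` (the
#' study scale: 45 x 33 grid, 1000 spins, 15 shapes, 3000 steps; cluster
#' scale).
#'
#' @param preset One of `"smoke"`, `"desk"`, `"full"`.
#' @param seed Master seed.
#' @param ... Overrides for any configuration field (`grid`, `timings`,
#'   `bmax_values`, `snr_values`, `n_spins`, `n_steps`, `Ts`,
#'   `perturb_per_base`, `sigma_frac`, `bmin`, `n_b`, `ivim`, `f_range`,
#'   `Dv_range`, `n_replicates`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(preset = c("desk", "smoke", "full"), seed = 1L,
                              ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    smoke = list(
      grid = build_grid(L_min = 20, L_max = 32, L_step = 3,
                        D0_min = 0.8, D0_max = 1.2, D0_step = 0.1),
      timings = data.frame(delta = c(20, 20), Delta = c(25, 75)),
      bmax_values = c(1000, 2000), snr_values = c(Inf, 20),
      n_spins = 60L, n_steps = 300L, perturb_per_base = 1L),
    desk = list(
      grid = build_grid(L_min = 11, L_max = 60, L_step = 3,
                        D0_min = 0.20, D0_max = 2.40, D0_step = 0.10),
      timings = study_timings(),
      bmax_values = c(1000, 1500, 2000), snr_values = c(Inf, 20),
      n_spins = 200L, n_steps = 1500L, perturb_per_base = 2L),
    full = list(
      grid = build_grid(),
      timings = study_timings(),
      bmax_values = c(1000, 1500, 2000),
      snr_values = c(Inf, 100, 80, 40, 20),
      n_spins = 1000L, n_steps = 3000L, perturb_per_base = 5L))
  base <- list(Ts = 140, sigma_frac = 0.1, bmin = 100, n_b = 7L,
               ivim = TRUE, f_range = c(0.05, 0.50), Dv_range = c(15, 60),
               n_replicates = 1L, seed = as.integer(seed), preset = preset)
  cfg <- c(cfg, base)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]  # flat replacement
  structure(cfg, class = "experiment_config")
}

grid_contexts <- function(cfg) {
  ctx <- merge(cfg$timings, data.frame(bmax = cfg$bmax_values))
  ctx <- ctx[order(ctx$delta, ctx$Delta, ctx$bmax), ]
  ctx$ctx_id <- seq_len(nrow(ctx))
  rownames(ctx) <- NULL
  ctx
}

#' Run the grid experiment
#'
#' Simulates walks for every grid (D0, L) pair and shape, synthesizes
#' direction-averaged intracellular signals for every (timing, bmax) context,
#' pools Omega neighborhoods with L^3 weights, applies IVIM contamination and
#' Rician noise, and fits the cumulant expansion per (centre, context, SNR,
#' replicate).
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print progress (default FALSE).
#' @return A `grid_results` list: `config`, `grid`, `contexts`,
#'   `s_intra` (centre x context x b array of noise-free pooled signals),
#'   `ivim` (per centre/context/replicate draws), `cumulants` (data frame),
#'   `clamped` (reflection-budget overruns).
#' @export
run_grid <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  grid <- cfg$grid
  nd <- length(grid$D0_values); nl <- length(grid$L_values)
  S <- 3L * cfg$perturb_per_base
  nt <- nrow(cfg$timings)
  nb <- cfg$n_b
  nbm <- length(cfg$bmax_values)
  dt <- cfg$Ts / cfg$n_steps
  master <- cfg$seed

  # per-timing gradient amplitudes for the union of b-values (nbm x nb)
  bmat <- vapply(cfg$bmax_values,
                 function(bm) make_bvalues(cfg$bmin, bm, nb), numeric(nb))

  # --- walks + per-cell direction-averaged signals ---------------------------
  SIG <- array(NA_real_, dim = c(nd, nl, S, nt, nbm, nb))
  clamped <- 0L
  for (j in seq_len(nl)) {
    L <- grid$L_values[j]
    shapes <- make_cell_shapes(L, cfg$perturb_per_base, cfg$sigma_frac,
                               seed = derive_seed(master, 10000L + j))
    for (s in seq_len(S)) {
      mesh <- shapes[[s]]
      for (i in seq_len(nd)) {
        counter <- 1000000 + (((j - 1) * S + (s - 1)) * nd + (i - 1))
        wc <- walk_config(D0 = grid$D0_values[i], N = cfg$n_spins,
                          Ts = cfg$Ts, n_steps = cfg$n_steps,
                          seed = derive_seed(master, counter))
        tr <- walk(mesh, wc, record = FALSE, timings = cfg$timings)
        clamped <- clamped + tr$clamped
        for (t in seq_len(nt)) {
          Gt <- gradient_amplitude(as.numeric(bmat),
                                   cfg$timings$delta[t], cfg$timings$Delta[t])
          cvec <- GAMMA_INTERNAL * dt * Gt
          acc <- 0
          for (d in 1:3) {
            phi <- outer(tr$A[, d, t], cvec)
            acc <- acc + sqrt(colMeans(cos(phi))^2 + colMeans(sin(phi))^2)
          }
          SIG[i, j, s, t, , ] <- t(matrix(acc / 3, nrow = nb))
        }
      }
    }
    if (verbose) message(sprintf("walks: L = %.1f um (%d/%d)", L, j, nl))
  }

  # --- Omega pooling ----------------------------------------------------------
  centers <- grid$centers
  ncen <- nrow(centers)
  h <- grid$omega_halfwidth
  s_intra <- array(NA_real_, dim = c(ncen, nt, nbm, nb))
  for (c in seq_len(ncen)) {
    ii <- centers$i[c] + (-h:h)
    jj <- centers$j[c] + (-h:h)
    wj <- grid$L_values[jj]^3
    wtot <- sum(wj) * length(ii) * S
    for (t in seq_len(nt)) for (m in seq_len(nbm)) {
      block <- SIG[ii, jj, , t, m, , drop = FALSE]   # (2h+1, 2h+1, S, 1, 1, nb)
      overj <- apply(block, c(2, 6), sum)            # sum over D0 members, shapes
      s_intra[c, t, m, ] <- colSums(overj * wj) / wtot
    }
  }

  # --- IVIM contamination, noise, cumulant fits -------------------------------
  ctx <- grid_contexts(cfg)
  rows <- vector("list", ncen * nrow(ctx) * length(cfg$snr_values) *
                   cfg$n_replicates)
  ivim_rows <- vector("list", ncen * nrow(ctx) * cfg$n_replicates)
  ri <- 0L; vi <- 0L
  for (c in seq_len(ncen)) {
    for (x in seq_len(nrow(ctx))) {
      t <- which(cfg$timings$delta == ctx$delta[x] &
                 cfg$timings$Delta == ctx$Delta[x])
      m <- which(cfg$bmax_values == ctx$bmax[x])
      b <- bmat[, m]
      si <- s_intra[c, t, m, ]
      for (r in seq_len(cfg$n_replicates)) {
        vi <- vi + 1L
        if (cfg$ivim) {
          dr <- draw_ivim(1, cfg$f_range, cfg$Dv_range,
                          seed = derive_seed(master,
                                             5000000 + (vi - 1)))
          s_cont <- add_ivim(si, b, dr$f, dr$Dv)
        } else {
          dr <- data.frame(f = 0, Dv = NA_real_)
          s_cont <- si
        }
        ivim_rows[[vi]] <- cbind(center = c, ctx_id = x, replicate = r, dr)
        for (sn in cfg$snr_values) {
          s_obs <- add_rician(s_cont, sn,
                              seed = derive_seed(master, 6000000 + ri))
          fit <- suppressWarnings(fit_dki(b, s_obs))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            center = c, i = centers$i[c], j = centers$j[c],
            d0 = centers$d0[c], l = centers$l[c],
            delta = ctx$delta[x], Delta = ctx$Delta[x], bmax = ctx$bmax[x],
            snr = sn, replicate = r, f = dr$f, Dv = dr$Dv,
            s0 = fit$s0, D = fit$D, K = fit$K,
            converged = fit$converged, clipped = fit$clipped)
        }
      }
    }
  }

  structure(list(config = cfg, grid = grid, contexts = ctx,
                 s_intra = s_intra, b_values = bmat,
                 ivim = do.call(rbind, ivim_rows),
                 cumulants = do.call(rbind, rows[seq_len(ri)]),
                 clamped = clamped),
            class = "grid_results")
}

#' Long-format table of pooled noise-free signals
#'
#' One row per (centre, context, b-value): the direction-averaged,
#' volume-weighted intracellular signal before contamination and noise.
#'
#' @param results A `grid_results`.
#' @return Data frame with `d0_center`, `l_center`, `delta`, `Delta`,
#'   `bmax`, `b`, `signal`.
#' @export
signal_table <- function(results) {
  cen <- results$grid$centers
  ctx <- results$contexts
  cfg <- results$config
  rows <- vector("list", nrow(cen) * nrow(ctx))
  k <- 0L
  for (x in seq_len(nrow(ctx))) {
    t <- which(cfg$timings$delta == ctx$delta[x] &
               cfg$timings$Delta == ctx$Delta[x])
    m <- which(cfg$bmax_values == ctx$bmax[x])
    b <- results$b_values[, m]
    for (c in seq_len(nrow(cen))) {
      k <- k + 1L
      rows[[k]] <- data.frame(d0_center = cen$d0[c], l_center = cen$l[c],
                              delta = ctx$delta[x], Delta = ctx$Delta[x],
                              bmax = ctx$bmax[x], b = b,
                              signal = results$s_intra[c, t, m, ])
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics of fitted D and K
#'
#' Median and central 95% range over grid centres for one (timing, bmax, SNR)
#' context.
#'
#' @param results A `grid_results`.
#' @param delta,Delta,bmax Context selectors.
#' @param snr SNR selector (`Inf` for noise-free).
#' @return One-row data frame with medians and 2.5/97.5 percentiles of D
#'   and K.
#' @export
summarize_dk <- function(results, delta, Delta, bmax, snr = Inf) {
  cu <- results$cumulants
  sel <- cu$delta == delta & cu$Delta == Delta & cu$bmax == bmax &
    cu$snr == snr
  if (sum(sel) < 2) stop("summarize_dk: fewer than 2 fitted rows selected")
  d <- cu$D[sel]; k <- cu$K[sel]
  data.frame(delta = delta, Delta = Delta, bmax = bmax, snr = snr,
             n = sum(sel),
             D_median = median(d),
             D_lo = quantile(d, 0.025, names = FALSE),
             D_hi = quantile(d, 0.975, names = FALSE),
             K_median = median(k),
             K_lo = quantile(k, 0.025, names = FALSE),
             K_hi = quantile(k, 0.975, names = FALSE))
}

grid_split <- function(results, seed = 20L) {
  ncen <- nrow(results$grid$centers)
  n_train <- if (ncen == 1189) 700L else max(3L, round(ncen * 700 / 1189))
  split_train_validation(seq_len(ncen), n_train = n_train, seed = seed)
}

#' Train and score the cell-size classifier for one context
#'
#' @param results A `grid_results`.
#' @param delta,Delta,bmax,snr Context selectors (SNR 20 in the study).
#' @param split Optional list with `train`/`validation` centre ids (default:
#'   a 700:489-proportioned split from `split_seed`).
#' @param split_seed Seed for the default split.
#' @param n_perm Permutations for the chance interval (0 to skip).
#' @param perm_seed Seed for the permutations.
#' @return List with `accuracy`, `per_class`, `confusion`, `interval`
#'   (`NULL` when `n_perm = 0`), `model`, `context`.
#' @export
classify_context <- function(results, delta, Delta, bmax, snr = 20,
                             split = NULL, split_seed = 20L,
                             n_perm = 0L, perm_seed = 7L) {
  cu <- results$cumulants
  sel <- cu$delta == delta & cu$Delta == Delta & cu$bmax == bmax &
    cu$snr == snr
  cu <- cu[sel, ]
  if (is.null(split)) split <- grid_split(results, seed = split_seed)
  tr <- cu[cu$center %in% split$train, ]
  va <- cu[cu$center %in% split$validation, ]
  lab_tr <- discretize_size(tr$l)
  lab_va <- discretize_size(va$l)
  context <- list(delta = delta, Delta = Delta, bmax = bmax, snr = snr)
  model <- fit_classifier(tr$D, tr$K, lab_tr, context = context)
  acc <- classify_accuracy(model, va$D, va$K, lab_va)
  interval <- NULL
  if (n_perm > 0)
    interval <- permutation_interval(tr$D, tr$K, lab_tr, va$D, va$K, lab_va,
                                     n_perm = n_perm, seed = perm_seed)
  c(acc, list(interval = interval, model = model, context = context))
}

#' Classification accuracy table over all contexts
#'
#' One row per (timing, bmax) at the given SNR, with permutation chance
#' intervals.
#'
#' @param results A `grid_results`.
#' @param snr SNR (default 20).
#' @param n_perm Permutations per context.
#' @param split_seed,perm_seed Seeds.
#' @return Data frame with accuracy and interval columns.
#' @export
reproduce_table1 <- function(results, snr = 20, n_perm = 200L,
                             split_seed = 20L, perm_seed = 7L) {
  ctx <- results$contexts
  split <- grid_split(results, seed = split_seed)
  do.call(rbind, lapply(seq_len(nrow(ctx)), function(x) {
    r <- classify_context(results, ctx$delta[x], ctx$Delta[x], ctx$bmax[x],
                          snr = snr, split = split, n_perm = n_perm,
                          perm_seed = derive_seed(perm_seed, x))
    data.frame(delta = ctx$delta[x], Delta = ctx$Delta[x], bmax = ctx$bmax[x],
               accuracy = r$accuracy,
               recall_small = r$per_class["small"],
               recall_medium = r$per_class["medium"],
               recall_large = r$per_class["large"],
               chance_lo = if (is.null(r$interval)) NA_real_ else r$interval$lo,
               chance_hi = if (is.null(r$interval)) NA_real_ else r$interval$hi)
  }))
}

#' Train PolyMap on one context of a grid run
#'
#' @param results A `grid_results`.
#' @param delta,Delta,bmax,snr Context selectors.
#' @param split,split_seed As in [classify_context()].
#' @return List with the fitted `model` and the validation `score` from
#'   [predict_and_score()].
#' @export
polymap_context <- function(results, delta, Delta, bmax, snr = 20,
                            split = NULL, split_seed = 20L) {
  cu <- results$cumulants
  sel <- cu$delta == delta & cu$Delta == Delta & cu$bmax == bmax &
    cu$snr == snr
  cu <- cu[sel, ]
  if (is.null(split)) split <- grid_split(results, seed = split_seed)
  tr <- cu[cu$center %in% split$train, ]
  va <- cu[cu$center %in% split$validation, ]
  context <- list(delta = delta, Delta = Delta, bmax = bmax, snr = snr)
  model <- fit_polymap(tr$D, tr$K, tr$d0, tr$l, context = context)
  score <- predict_and_score(model, va$D, va$K, va$d0, va$l, context = context)
  list(model = model, score = score, split = split)
}

#' Calibration configuration lattice
#'
#' Builds the set of (D0, L, delta, Delta) configurations on which the
#' wide-pulse constants are calibrated: a uniform candidate lattice over the
#' study grid ranges crossed with the five gradient timings, restricted to
#' the regime where the truncated wide-pulse expansion is self-consistent,
#' u = L^2 / (D0 delta) in `u_window`. The upper cut is the positivity bound
#' of the two-term ADC (beyond u = c0/c1 the model predicts negative
#' diffusivity, so it cannot be calibrated there); the lower cut excludes the
#' deep motional-narrowing regime, where the apparent geometry constants are
#' several-fold larger and the fit would not describe the cells the model is
#' deployed on. If more candidates pass the window than `n_configs`, an
#' evenly spaced (by u) deterministic subset is taken.
#'
#' @param n_configs Number of configurations (default 400).
#' @param D0_range,L_range Lattice ranges (study grid defaults).
#' @param n_D0,n_L Candidate lattice resolution.
#' @param timings Data frame of delta/Delta pairs (default [study_timings()]).
#' @param u_window Validity window for u = L^2/(D0 delta).
#' @return Data frame with `d0`, `l`, `delta`, `Delta`, `u`.
#' @export
calibration_lattice <- function(n_configs = 400L,
                                D0_range = c(0.2, 2.4), L_range = c(11, 59),
                                n_D0 = 16L, n_L = 16L,
                                timings = study_timings(),
                                u_window = c(20, 110)) {
  cand <- expand.grid(d0 = seq(D0_range[1], D0_range[2], length.out = n_D0),
                      l = seq(L_range[1], L_range[2], length.out = n_L),
                      t = seq_len(nrow(timings)), KEEP.OUT.ATTRS = FALSE)
  cand$delta <- timings$delta[cand$t]
  cand$Delta <- timings$Delta[cand$t]
  cand$u <- cand$l^2 / (cand$d0 * cand$delta)
  cand <- cand[cand$u >= u_window[1] & cand$u <= u_window[2], ]
  cand <- cand[order(cand$u), ]
  if (nrow(cand) < n_configs)
    stop("calibration_lattice: candidate lattice too coarse for n_configs")
  idx <- unique(round(seq(1, nrow(cand), length.out = n_configs)))
  cand <- cand[idx, c("d0", "l", "delta", "Delta", "u")]
  rownames(cand) <- NULL
  cand
}

#' Simulated ADC table for the wide-pulse calibration
#'
#' Simulates noise-free intracellular signals for each calibration
#' configuration, pools the shape ensemble (equal sizes, so plain means),
#' direction-averages, and extracts a mono-exponential ADC from the low-b
#' decay (b <= `bmax`).
#'
#' @param configs Data frame with `d0`, `l`, `delta`, `Delta` (default
#'   [calibration_lattice()], 400 configurations).
#' @param n_spins,n_steps,Ts,perturb_per_base,sigma_frac Simulation scale.
#' @param bmin,bmax,n_b ADC-extraction b-range (s/mm^2).
#' @param seed Master seed.
#' @return `configs` with an `adc` column appended.
#' @export
simulate_adc_table <- function(configs = calibration_lattice(),
                               n_spins = 300L, n_steps = 1500L, Ts = 140,
                               perturb_per_base = 2L, sigma_frac = 0.1,
                               bmin = 100, bmax = 1000, n_b = 7L,
                               seed = 1L) {
  b <- make_bvalues(bmin, bmax, n_b)
  dt <- Ts / n_steps
  S <- 3L * perturb_per_base
  configs$adc <- NA_real_
  pairs <- unique(configs[, c("d0", "l")])
  for (p in seq_len(nrow(pairs))) {
    sel <- which(configs$d0 == pairs$d0[p] & configs$l == pairs$l[p])
    timings <- unique(configs[sel, c("delta", "Delta")])
    shapes <- make_cell_shapes(pairs$l[p], perturb_per_base, sigma_frac,
                               seed = derive_seed(seed, 20000L + p))
    sig <- matrix(0, nrow = nrow(timings), ncol = n_b)
    for (s in seq_len(S)) {
      wc <- walk_config(D0 = pairs$d0[p], N = n_spins, Ts = Ts,
                        n_steps = n_steps,
                        seed = derive_seed(seed, 3000000 + (p - 1) * S + s))
      tr <- walk(shapes[[s]], wc, record = FALSE, timings = timings)
      for (t in seq_len(nrow(timings))) {
        G <- gradient_amplitude(b, timings$delta[t], timings$Delta[t])
        cvec <- GAMMA_INTERNAL * dt * G
        acc <- 0
        for (d in 1:3) {
          phi <- outer(tr$A[, d, t], cvec)
          acc <- acc + sqrt(colMeans(cos(phi))^2 + colMeans(sin(phi))^2)
        }
        sig[t, ] <- sig[t, ] + acc / 3
      }
    }
    sig <- sig / S
    for (k in seq_along(sel)) {
      t <- which(timings$delta == configs$delta[sel[k]] &
                 timings$Delta == configs$Delta[sel[k]])
      configs$adc[sel[k]] <- fit_adc(b, sig[t, ])$adc
    }
  }
  configs
}

#' Calibrate the SigFit constants from simulation
#'
#' Convenience wrapper: [simulate_adc_table()] on the default calibration
#' lattice, then [calibrate_constants()] with per-configuration
#' (`"normalized"`) weighting.
#'
#' @param ... Passed to [simulate_adc_table()].
#' @param weights Passed to [calibrate_constants()] (default `"normalized"`).
#' @return A `sigfit_model`.
#' @export
calibrate_sigfit <- function(..., weights = "normalized") {
  tab <- simulate_adc_table(...)
  calibrate_constants(tab$adc, tab$d0, tab$l, tab$delta, tab$Delta,
                      weights = weights,
                      calibration = list(n = nrow(tab),
                                         u_range = range(tab$l^2 / (tab$d0 * tab$delta))))
}
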
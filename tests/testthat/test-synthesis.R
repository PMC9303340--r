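test_that("zero gradient and static spins rephase to unit signal", {
  cfg <- walk_config(D0 = 0, N = 50L, Ts = 140, n_steps = 500L, seed = 2)
  tr <- walk(small_cell(), cfg, record = TRUE)
  w0 <- matrix(0, nrow = 501, ncol = 3)
  expect_equal(phase_signal(tr, w0), 1)
  # static spins under a balanced waveform: perfect rephasing
  wv <- effective_waveform(20, 40, 1500, c(1, 0, 0), tr$dt, 500)
  expect_equal(phase_signal(tr, wv), 1, tolerance = 1e-12)
})

test_that("free diffusion attenuates as exp(-b D0) within Monte Carlo error", {
  tr <- free_walk()
  for (b in c(500, 1000)) {
    wv <- effective_waveform(20, 75, b, c(0, 0, 1), tr$dt, tr$n_steps)
    ps <- phase_signal(tr, wv, return_phases = TRUE)
    se <- sd(cos(ps$phases)) / sqrt(length(ps$phases))
    expect_lt(abs(ps$signal - exp(-b * 1e-3 * 1.0)), 3 * se + 1e-3)
  }
})

test_that("narrow pulses in a box reproduce the reflecting-segment closed form", {
  # unperturbed square prism = box with widths L/sqrt(2) along the base
  # diagonals and L along z
  m <- make_prism(4, 20)
  cfg <- walk_config(D0 = 1.0, N = 4000L, Ts = 140, n_steps = 3000L, seed = 7)
  tr <- walk(m, cfg, record = TRUE)
  for (b in c(1000, 2000)) {
    G <- gradient_amplitude(b, 1, 75)
    q <- hepatosim:::GAMMA_INTERNAL * G * 1
    for (dir in list(list(v = c(1, 1, 0) / sqrt(2), a = 20 / sqrt(2)),
                     list(v = c(0, 0, 1), a = 20))) {
      s_sim <- phase_signal(tr, effective_waveform(1, 75, b, dir$v, tr$dt, 3000))
      s_th <- narrow_pulse_segment(q, 75, dir$a, 1.0)
      expect_equal(s_sim / s_th, 1, tolerance = 0.05)
    }
  }
})

test_that("volume-weighted pooling is a proper convex combination", {
  expect_equal(pooled_signal(rep(0.7, 25), rep(30, 25)), 0.7)
  s <- c(0.2, 0.9)
  L <- c(10, 50)
  w <- L^3 / sum(L^3)
  expect_equal(pooled_signal(s, L), sum(w * s))
  expect_equal(sum(w), 1)
  expect_error(pooled_signal(c(0.1, NA), c(10, 20)), "missing")
})

test_that("direction averaging is the arithmetic mean", {
  expect_equal(direction_average(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(direction_average(0.5), 0.5)
  expect_error(direction_average(numeric(0)), "no direction")
})

test_that("IVIM contamination follows the two-pool mixture", {
  expect_equal(add_ivim(0.63, 500, 0, 20), 0.63)
  expect_equal(add_ivim(1, 0, 0.3, 20), 1)
  expect_equal(add_ivim(1, 100, 0.5, 20), 0.5 * exp(-2) + 0.5)
  expect_error(add_ivim(0.5, 100, 1.2, 20), "0, 1")
  d <- draw_ivim(500, seed = 3)
  expect_true(all(d$f >= 0.05 & d$f <= 0.50))
  expect_true(all(d$Dv >= 15 & d$Dv <= 60))
  expect_identical(draw_ivim(5, seed = 9), draw_ivim(5, seed = 9))
})

test_that("Rician noise has the magnitude-reconstruction moments", {
  expect_identical(add_rician(c(0.3, 0.8), Inf), c(0.3, 0.8))
  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  sigma <- 1 / 20
  draws <- add_rician(rep(0, 1e5), 20, seed = 5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - sigma * sqrt(pi / 2)), 3 * se)
  # strong signal: mean approx sqrt(s^2 + sigma^2)
  s <- 0.9
  draws2 <- add_rician(rep(s, 1e5), 20, seed = 6)
  se2 <- sd(draws2) / sqrt(length(draws2))
  expect_lt(abs(mean(draws2) - sqrt(s^2 + sigma^2)), 3 * se2 + 1e-4)
  expect_error(add_rician(0.5, -1), "positive")
})

test_that("restricted signals never exceed unity and weaken with cell size", {
  # motional narrowing: at fixed D0 = 2, delta/Delta = 20/75, attenuation at
  # b = 2000 grows with L (restriction weakens) over 11 -> 35 um
  tmg <- data.frame(delta = 20, Delta = 75)
  sig <- vapply(c(11, 20, 27.5, 35), function(L) {
    m <- make_prism(6, L)
    cfg <- walk_config(D0 = 2.0, N = 400L, Ts = 140, n_steps = 1500L,
                       seed = 31L)
    tr <- walk(m, cfg, record = FALSE, timings = tmg)
    G <- gradient_amplitude(2000, 20, 75)
    mean(vapply(1:3, function(d)
      lobe_signal(tr$A[, , 1], G, tr$dt, diag(3)[d, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(sig <= 1))
  expect_true(all(diff(sig) < 0))  # larger cells attenuate more
})
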
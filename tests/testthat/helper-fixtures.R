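# Shared fixtures: built once per test run, in code.

# published wide-pulse geometry constants, used where a test needs plausible
# SigFit constants without running a calibration
sigfit_ref_model <- function() {
  structure(list(c0 = 1.342e-3, c1 = 1.259e-5, calibration = NULL),
            class = "sigfit_model")
}

# free-diffusion walk in a huge box (no wall ever reached at this scale)
free_walk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      big <- make_prism(4, 4000)
      cfg <- walk_config(D0 = 1.0, N = 3000L, Ts = 140, n_steps = 1000L,
                        seed = 11L)
      cache <<- walk(big, cfg, record = TRUE,
                     timings = data.frame(delta = 20, Delta = 75))
    }
    cache
  }
})

# small perturbed cell + walk reused by containment/signal tests
small_cell <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- perturb_cell(make_prism(5, 18), 0.1, seed = 3L)
    cache
  }
})
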
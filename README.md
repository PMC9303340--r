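# hepatosim

Monte Carlo simulation of liver diffusion MRI and estimation of hepatocyte
microstructure from clinical-style acquisitions.

## What it is for

Clinical liver diffusion MRI typically offers a single diffusion encoding
(PGSE, gradient duration δ and separation Δ), b-values up to ~2000 s/mm² and
one fixed diffusion time. From such data one can fit the second-order
cumulant expansion

    ln s = ln s0 − b·D + (1/6)·K·(b·D)²

for the apparent diffusion coefficient D (µm²/ms) and apparent kurtosis K.
`hepatosim` asks, in silico, how much those two numbers say about hepatocyte
microstructure — the intrinsic intracellular diffusivity D0 (µm²/ms) and the
cell size L (µm) — and provides the estimators to invert them:

* a **mesh-bounded Monte Carlo simulator**: impermeable synthetic hepatocytes
  (perturbed square/pentagonal/hexagonal prisms, 15 shapes per size), spins
  taking fixed-length steps with elastic (specular) reflection at the walls;
* **signal synthesis**: per-spin phase accrual along effective PGSE
  waveforms, L³ volume-weighted pooling over a (D0, L) neighborhood,
  three-direction averaging, IVIM perfusion contamination
  s = f·e^(−b·Dv) + (1−f)·s_intra, and Rician noise at a chosen SNR;
* **cumulant fitting** (bounded nonlinear least squares on the log signal);
* **PolyMap**: degree-3 bivariate polynomial regression (D, K) → D0 and
  (D, K) → L, trained on 700 of the 1189 grid centres, validated on 489;
* **SigFit**: the biophysical alternative — a calibrated wide-pulse signal
  model s = s0·exp(−b·[c0·L⁴/(D0·δ·(Δ−δ/3)) − c1·L⁶/(D0²·δ²·(Δ−δ/3))]),
  fitted jointly for (s0, D0, L) or with D0 pinned;
* a three-class **cell-size classifier** (small ≤ 28 µm < medium ≤ 42 µm <
  large) with permutation-derived chance intervals;
* the **histological cell-size index** Lhisto = (⟨l⁷⟩/⟨l³⟩)^(1/4), the
  moment ratio that matches what the volume-weighted MRI signal actually
  sees in a patch of segmented cells.

It is aimed at diffusion-MRI methodologists who want a controlled testbed
for fixed-diffusion-time cell-size estimation in liver-like tissue.

## Worked example

Simulate one 30 µm hepatocyte at D0 = 1 µm²/ms, synthesize a 7-shell
δ/Δ = 20/75 ms protocol, and fit it:

```r
library(hepatosim)

cell <- perturb_cell(make_prism(6, 30), sigma_frac = 0.1, seed = 7)
mesh_volume(cell)                     # 19815.9 um^3

cfg <- walk_config(D0 = 1.0, N = 500, Ts = 140, n_steps = 1500, seed = 1)
tr  <- walk(cell, cfg, record = FALSE,
            timings = data.frame(delta = 20, Delta = 75))

b <- make_bvalues(100, 2000, 7)
s <- vapply(b, function(bb) {
  G <- gradient_amplitude(bb, 20, 75)
  mean(vapply(1:3, function(d)
    lobe_signal(tr$A[, , 1], G, tr$dt, diag(3)[d, ]), numeric(1)))
}, numeric(1))

fit_dki(b, s)
#> DKI fit: s0 = 1.0000, D = 0.4588 um^2/ms, K = 0.1686 (resid 0.000674)

mod <- calibrate_sigfit(seed = 1)     # c0/c1 from 400 simulated configs
fit_signal(b, s, 20, 75, mod, fixed_D0 = 1.0)
#> SigFit: s0 = 0.9976, D0 = 1.000, L = 29.71 um (ADC 0.4482, resid 0.00325)
```

Restriction drags the apparent D to 0.46 — less than half the intrinsic
diffusivity — with a small positive kurtosis; the calibrated signal model,
given the true D0, reads the cell size back to within 1%. (The SigFit line
above uses the published-magnitude constants; a fresh calibration lands
within ~10% of them and changes the example's L by well under a micron.)

The full grid experiment (simulate → pool → contaminate → fit → map →
classify) is one call per scale preset:

```r
res <- run_grid(experiment_config("desk", seed = 101))
summarize_dk(res, 20, 25, 1000, snr = Inf)   # median/95% range of D and K
classify_context(res, 20, 75, 1500, snr = 20, n_perm = 200)
```

A thin command-line front end lives in `inst/cli/hepatosim.R`
(`simulate-walks`, `fit-dki`, `train-polymap`, `apply-polymap`, `lhisto`,
`run`).

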
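---
title: "Estimating hepatocyte size and diffusivity from diffusion-MRI cumulants at fixed diffusion time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hepatocyte size and diffusivity from diffusion-MRI cumulants at fixed diffusion time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hepatosim)
```

## The problem

Clinical liver diffusion MRI is usually acquired with a single diffusion
encoding (PGSE: two gradient lobes of duration $\delta$ separated by
$\Delta$), a handful of b-values up to about 2000 s/mm², and one fixed
diffusion time. The question this package studies in silico is whether such
minimal protocols retain usable information about hepatocyte microstructure —
specifically the intrinsic intracellular diffusivity $D_0$ (µm²/ms) and the
cell size $L$ (µm) — through the two signal cumulants that such data can
support: the apparent diffusion coefficient $D$ and the apparent kurtosis
$K$.

The model system is deliberately reduced: water diffuses inside impermeable,
mesh-bounded cells (no extracellular/extravascular compartment, no
transcytolemmal exchange, no relaxation weighting), perfusion enters only as
an IVIM-like partial-volume term, and noise is Rician. What passing tests
show is therefore internal consistency of this synthetic world — not that
real livers obey it. The package's own account of where that assumption is
reasonable (tightly packed hepatocytes, 70–85% of liver volume, intracellular
residence times longer than the diffusion times probed) is a hypothesis the
ex-vivo literature supports but this code cannot prove.

## The pipeline

1. **Geometry** (`make_prism()`, `perturb_cell()`, `make_cell_shapes()`).
   Hepatocytes are right prisms with regular square/pentagonal/hexagonal
   bases; the characteristic length $L$ is both the prism height and the
   diameter of the base circumcircle. Shape variability comes from in-plane
   normal displacements of the base-polygon vertices (sd $0.1L$), re-extruded
   to height $L$; 3 base types × 5 perturbations give the 15-shape ensemble.
   The perturbation is applied to the base footprint only (both bases share
   it): this reading guarantees a watertight extrusion, and the displacement
   dimensionality is not uniquely fixed by the construction described above —
   it is a design choice, recorded here.

2. **Microstructure grid** (`build_grid()`). 33 sizes $L \in [11, 59]$ µm
   (step 1.5) × 45 diffusivities $D_0 \in [0.20, 2.40]$ µm²/ms (step 0.05).
   Each voxel-level signal pools a 5×5 neighborhood $\Omega$ (±2 grid steps
   per axis) around its centre, mimicking intra-voxel heterogeneity; the
   1189 valid centres are those whose neighborhood stays on the grid.

3. **Random walks** (`walk()`). $N$ spins per cell, seeded uniformly by
   rejection sampling, take fixed-length steps $\sqrt{6 D_0 \, dt}$ in
   directions uniform on the sphere and reflect specularly (elastically) at
   the faces, recursively within a step. The fixed-length convention matches
   the Monte Carlo engines standard in this field; both it and Gaussian
   increments converge to the same propagator as $dt \to 0$. Defaults:
   $T_s = 140$ ms in 3000 steps. Validation: free diffusion reproduces
   $\langle r^2 \rangle = 6 D_0 t$ and $e^{-bD_0}$ signals; a box geometry
   reproduces the product of 1-D reflecting-segment narrow-pulse closed
   forms (`narrow_pulse_segment()`) within 5%; confined walks reach the
   uniform-difference variance $a^2/6$ per axis.

4. **Signal synthesis** (`phase_signal()`, `pooled_signal()`, `add_ivim()`,
   `add_rician()`). Per-spin phases are left-Riemann sums
   $\varphi = \gamma\, dt \sum_t \mathbf{G}(t)^\top \mathbf{r}(t)$ over the
   *effective* (post-refocusing) waveform; the per-cell signal is the
   magnitude of the mean phasor. Cells are pooled over $\Omega$ and the
   shape ensemble with weights $L^3$ (the water volume each cell
   contributes), normalized to 1; three orthogonal gradient directions are
   averaged. Perfusion contamination follows
   $s = f e^{-b D_v} + (1-f)\, s_\text{intra}$ with $f \sim U(0.05, 0.50)$
   and $D_v \sim U(15, 60)$ µm²/ms, one draw per (centre, protocol,
   replicate); uniformity is an assumption, only the ranges being given.
   Rician noise $\sqrt{(s+\epsilon_1)^2 + \epsilon_2^2}$,
   $\sigma = 1/\text{SNR}$ on the $s(0)=1$ scale, is applied after
   direction-averaging and contamination (matching the "SNR at b = 0"
   convention). "Noise-free" throughout means SNR $= \infty$ with the IVIM
   term still present.

5. **Cumulant fitting** (`fit_dki()`). Bounded nonlinear least squares on
   $\ln s = \ln s_0 - bD + \tfrac{1}{6} K (bD)^2$ with
   $0 \le s_0 \le 1$, $0 \le D \le 2.4$, $-5 \le K \le 10$, initialized from
   an ordinary least-squares quadratic in $b$; b-values are converted to
   ms/µm² internally so that $D$ carries µm²/ms. Signals below $10^{-6}$ are
   clipped before the log (Rician magnitudes are nonnegative but can be
   tiny). Seven nonzero shells, uniform on $[100, b_\text{max}]$ s/mm².

6. **Estimators.** *PolyMap* (`fit_polymap()`) is plain least squares of
   $D_0$ and $L$ on the ten monomials
   $1, D, K, DK, D^2, K^2, D^2K, DK^2, D^3, K^3$, trained on 700 of the 1189
   centres and validated on the remaining 489. The mapping is specific to
   the (protocol, $b_\text{max}$, SNR) context it was trained in, and the
   model object refuses silent cross-context use. *SigFit*
   (`fit_signal()`) fits $s = s_0 \exp(-b \,\text{ADC}(D_0, L))$ with the
   wide-pulse two-term form
   $\text{ADC} = c_0 L^4 / (D_0 \delta (\Delta - \delta/3)) -
   c_1 L^6 / (D_0^2 \delta^2 (\Delta - \delta/3))$ — the second-term
   denominator is the unique dimensionally consistent reading (µm²/ms).
   Because a single fixed-$(\delta, \Delta)$ decay is mono-exponential in
   $b$, only $(s_0, \text{ADC})$ are identifiable and the joint fit returns
   a point on the $\text{ADC}(D_0, L) = \text{const}$ ridge, explored by a
   36-point multi-start (ties broken toward smaller $L$); pinning $D_0$
   restores identifiability of $L$, at the price of strong sensitivity to
   the pin (the two-population test shows the estimated-size contrast can
   change materially, even invert, across pins).

7. **Classification** (`fit_classifier()`, `permutation_interval()`). Sizes
   are discretized small ($L \le 28$), medium ($28 < L \le 42$), large
   ($L > 42$); a multinomial logistic model on the same ten-monomial basis
   is trained at SNR 20 and scored on the validation centres. Chance levels
   come from retraining on label permutations of the training set
   (validation labels intact), reporting the central 95% interval.

8. **Histology index** (`lhisto()`).
   $L_\text{histo} = (\langle l^7 \rangle / \langle l^3 \rangle)^{1/4}$ over
   per-patch cell diameters: the volume-weighted MRI signal is dominated by
   $l^3$-weighted, $l^4$-attenuated cells, so this moment ratio — not the
   plain mean — is the MRI-matched size index. Plain arithmetic means are
   used; diameters arrive pre-extracted, so no area weighting is applied.

## Calibration of the wide-pulse constants

The constants $c_0, c_1$ are geometry-specific and are calibrated on
simulated noise-free intracellular ADCs (mono-exponential fits to the
$b \le 1000$ s/mm² decay) from 400 unique $(D_0, L, \delta, \Delta)$
configurations (`calibration_lattice()`, `calibrate_sigfit()`). Two choices
matter and are the package's own:

* **Which configurations.** The two-term expansion predicts a *negative* ADC
  once $u = L^2/(D_0 \delta)$ exceeds $c_0/c_1$ (about 107 for constants of
  the calibrated magnitude), so it cannot describe — and should not be
  calibrated on — configurations beyond that bound. At the other end,
  $u \lesssim 20$ is the deep motional-narrowing regime, where the apparent
  geometry constants are several-fold larger and a pooled fit would not
  describe the moderately restricted cells the model is deployed on. The
  default lattice therefore samples $20 \le u \le 110$, uniformly over the
  grid ranges and the five timings.

* **How each configuration is weighted.** Plain least squares through the
  origin is dominated by the rows with the largest $L^4$ regressor; the
  default instead gives each configuration equal voice by regressing the
  normalized ADC, $\text{ADC} \cdot D_0 \delta (\Delta - \delta/3) / L^4$,
  linearly on $u$ (`weights = "normalized"`). Both the window and the
  weighting are exposed as arguments; with the defaults, the calibration
  lands on $c_0 \approx 1.25\times10^{-3}$, $c_1 \approx 1.28\times10^{-5}$
  at desk scale — within 10% of the published constants for this cell
  ensemble, and stable across seeds and extraction b-ranges.

## Problem sizes, numerical choices, degenerate inputs

* Presets (`experiment_config()`): `full` is the study scale (45×33 grid,
  1000 spins, 15 shapes, 3000 steps, five SNRs) and is cluster-scale work;
  `desk` thins the lattice to every second point (23×17, 247 centres;
  $\Omega$ stays ±2 *grid* steps, i.e. ±0.10/0.20 µm²/ms × ±3/6 µm), with
  200 spins, 6 shapes and 1500 steps — this is the scale at which the test
  suite and the acceptance script reproduce the reported medians and the
  classification headline on one CPU in minutes; `smoke` is a 1-centre
  pipeline check. Reported medians at desk scale carry a few-percent Monte
  Carlo wobble; the tolerances quoted in the tests absorb it.
* Walks: reflections recurse up to 20 times within one step; a spin
  exceeding that is reverted to its pre-step position and counted
  (`$clamped`). A plane-distance cull and an inscribed safety ball keep the
  collision test away from the hot path. Containment is verified to
  $10^{-6}$ µm.
* Degenerate fits: all-equal signals flag `degenerate`; bound-hitting
  estimates flag `at_bound`; non-positive signals are clipped with a
  warning; classifier separation falls back to a $10^{-6}$ ridge.
* Ties in the SigFit multi-start (residuals within $10^{-6}$ relative) go to
  the smaller $L$.
* Determinism: every stochastic stage derives its seed from the master seed
  via a counter scheme (`derive_seed()`), so any subset of a run can be
  reproduced in isolation; reruns are byte-identical.

## Known limitations

* The synthetic world omits extracellular/extravascular water and exchange;
  where those matter (fibrosis, oedema), $(D, K)$ keep sensitivity but lose
  specificity to $(D_0, L)$.
* PolyMap is an interpolator: it inherits the training grid's support,
  over-estimates at the small end and under-estimates at the large end of
  both targets, and must be retrained per protocol and SNR.
* SigFit's wide-pulse form is used far from its asymptotic regime for large
  cells; its joint fit is ridge-degenerate by construction at fixed
  diffusion time. Varying-diffusion-time acquisitions are the principled
  fix and are out of scope here.
* Mesh perturbation applies to the base footprint only; histology-derived
  meshes, permeable membranes and non-prismatic cells are not modelled.
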
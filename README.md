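# parsim

Timing algebra and ultralow-SNR reconstruction for **parallel
acquisition-readout structured illumination microscopy** (SIM) on
rolling-shutter sCMOS cameras, with a forward simulator that makes every
stage testable without instrument data.

In this acquisition scheme a galvo pair projects the six (2-angle-3-phase)
or nine (3-angle-3-phase) pattern images sequentially onto a 2×3 grid of
sub-ROIs inside one opened sensor region, so the rolling-shutter readout
time of earlier sub-ROIs is reused as exposure time of later ones. That
buys an order-of-magnitude frame-rate gain at the price of (i) a strict
synchronization algebra between the SLM switching duration T_ii, the galvo
dwell T_i and the line readout time t_row, and (ii) sub-millisecond
exposures whose raw frames sit at or below 0 dB SNR, where conventional
SIM parameter estimation breaks down.

The package provides:

* **Timing** — row budgets `ceil(n·T_ii/t_row)` (4-row granularity),
  raw/SIM frame rates, information flux, rolling-reconstruction cadence,
  plan validation (`T_ii + T_D3 = T_i`, crosstalk bound `T_ii ≤ T_i`,
  half-set readout bound `N·t_row/2 ≥ 3·T_ii`), and the published SLM
  presets (`slm_presets()`, `preset_plan()`).
* **Simulator** — scenes, ideal-pupil OTF, sinusoidal-excitation rendering
  with Poisson + read noise calibrated to a target SNR, frame assembly
  with galvo-jitter shifts, TIFF/JSON dataset round-trip
  (`simulate_sim_stack()`, `simulate_dataset()`).
* **Preprocessing** — cropping, leave-one-out phase-correlation
  registration, histogram-mode background estimation, Gaussian-ramp edge
  apodization, Richardson–Lucy pre-filtering.
* **Parameter estimation** — the low-SNR chain: zero-order-free difference
  spectra, phase-difference estimation by minimizing the weighted
  cross-correlations of the candidate-separated orders
  (argmin over φ ∈ (π/3, π)), ring-mask (0.5–1.1 k_c) + ±2.5° angular-prior
  coarse k search, OTF-compensated sub-pixel refinement
  (argmax_k |Σ S_central·conj(S_side(k+k_θ))| on the overlap), closed-form
  phase/modulation refresh.
* **Reconstruction** — exact 3×3 order separation, phase-ramp order
  shifting on the 2× grid, generalized Wiener fusion with zero-order
  notches and triangular apodization to k_c + |k_θ|, synthesized SIM
  OTF/PSF, final RL deconvolution, rolling (sliding-window)
  reconstruction. `sim_reconstruct()` returns a classed object with
  `print`/`summary`/`coef`/`plot` methods.
* **Metrics** — region-based SNR (`10·log10(Signal/MSE_noise)`), Gaussian
  FWHM measurement, tubulation-track displacement/velocity statistics with
  downsampling comparison.

A thin CLI lives at `inst/cli/parsim.R`
(`Rscript parsim.R timing --slm qxga --exposure 200`, `simulate`,
`reconstruct`, `snr`, `track`).

## Worked example

```r
library(parsim)

# the 0.2 ms QXGA operating point
plan <- preset_plan("qxga", 200)
min_opened_rows(plan$t_ii, plan$t_row, 6)   # 364 rows
max_raw_framerate(plan$t_ii)                # 1697 Hz raw pattern rate
sim_framerate(0, 0, plan$t_i, 6)            # 256 Hz whole-frame SIM rate
info_flux(256, 1352, 384)                   # 132.9 MPixels/s
rolling_cadence(4.9, 6, 3)$framerate        # 408.16 Hz with 3-rolling

# simulate a 2-angle-3-phase stack at -2 dB and reconstruct it
sim <- simulate_sim_stack(seed = 1, snr_db = -2, shape = c(192, 192))
stk <- subroi_stack(sim$images)
rec <- sim_reconstruct(stk, sim$optics, sim$pattern_nominal$angles)
rec
#> SIM reconstruction: 384 x 384 super-resolved image (2x grid)
#>   extended cutoff 0.2949 c/px on the fine grid (nominal gain 1.77x), max imag residual 3.08e-03
#> Illumination estimates:
#>             ky         kx magnitude angle_deg    phi21    phi31 global_phase modulation
#> [1,] 0.1482333  0.2083680 0.2557153   35.4281 1.850215 4.237861    -1.761431  0.7839074
#> [2,] 0.2083891 -0.1483003 0.2557714  125.4376 2.050015 4.131615     2.132032  0.7760268
```

`coef(rec)` rows report, per pattern angle, the estimated fringe k-vector
(cycles/pixel) and its angle, the two phase differences, the global
illumination phase and the modulation depth — compare against
`sim$truth`. On bead scenes `resolution_study()` measures the SR/widefield
FWHM ratio (≈0.25 at 0 dB, i.e. a ≥1.6× resolution gain), and
`recovery_study()` quantifies estimator accuracy over seeded low-SNR
stacks together with the fixed-phase/notch-only baseline.

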
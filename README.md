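# spadflim

Processing chain for NAD(P)H fluorescence lifetime imaging (FLIM) with
time-correlated SPAD array cameras on light-sheet microscopes — and a
synthetic acquisition simulator so every stage can be validated without the
instrument.

## Who this is for

Labs doing label-free metabolic imaging measure the autofluorescence decay
of NAD(P)H, whose lifetime separates the free coenzyme (short component,
τ₁ ≈ 0.3–0.5 ns) from the protein-bound pool (long component,
τ₂ ≈ 2–3 ns). Widefield SPAD arrays with a time-to-digital converter (TDC)
per pixel make this feasible at camera speed, but the raw data need
sensor-specific corrections before any lifetime is trustworthy. This package
implements that full chain in R:

1. **TCSPC data model** — per-photon event streams (row, col, TDC code) in a
   documented HDF5 dialect, 3D decay histograms on a 486-bin / 41.1 ps /
   50 MHz time axis.
2. **Sensor calibration** — per-pixel dark count rate (DCR) from the last
   2 ns of each decay; inter-pixel timing skew (up to ~60 bins ≈ 2.5 ns) by
   Pearson-normalized circular cross-correlation against a reference decay,
   corrected with exact count-conserving circular shifts; screamer/dead
   pixel classification.
3. **Lifetime fitting** — iterative reconvolution least squares of
   `I(t) = α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂)` with a periodic (wrapped) exponential
   kernel convolved with the IRF (380 ps FWHM class), fixed tail-based dark
   offset, iteratively reweighted Poisson-variance weights, and the
   amplitude-weighted mean lifetime `τ_m = α₁τ₁ + α₂τ₂` per pixel.
4. **Image fusion and per-cell statistics** — bilinear upscaling of lifetime
   maps to the 2×-finer CMOS intensity grid, threshold + 8-connected
   component cell masks, coverage-based downsampling to the SPAD grid, tidy
   per-cell statistics.
5. **Throughput/radiometry budgets** — system count rates, speed-advantage
   ratios, peak irradiance and light dose for scanning vs widefield
   geometries.
6. **Time-course analysis** — linear trend test (slope, F, p) for metabolic
   perturbation experiments.
7. **Simulator** — seeded phantoms and full acquisitions (photon streams,
   histograms, CMOS companions, IRF acquisitions, cyanide-type time courses)
   with injected ground truth for recovery testing.

## Worked example

Fit one noisy pixel decay (5000 photons, biexponential truth
α₁ = 0.75, τ₁ = 0.4 ns, τ₂ = 2.6 ns, dark offset 2 counts/bin):

```r
library(spadflim)
ax  <- make_time_axis(50e6, 41.1)   # <time_axis> 486 bins of 41.1 ps over a 20 ns period
irf <- gaussian_irf(380, ax, t0_ns = 1)
set.seed(1)
decay <- rpois(ax$n_bins, model_decay(0.75, 0.4, 2.6, amplitude = 5000,
                                      offset = 2, irf = irf, axis = ax))
fit_pixel(decay, irf, ax, model = "bi", offset = 2)
#> <flim_fit> bi-exponential: tau_m = 0.910 ns (chi2_red 1.018, converged)
#>   alpha1 0.731  tau1 0.385 ns  tau2 2.333 ns  photons 5044
```

The fitted mean lifetime (0.910 ns) sits within noise of the generating
truth (τ_m = 0.75·0.4 + 0.25·2.6 = 0.95 ns); a reduced χ² near 1 says the
Poisson noise model fits. Whole frames go through `calibrate_sensor()` +
`fit_image()`, and `run_pipeline()` chains simulate → calibrate → fit →
fuse → per-cell stats → trend test (see the methods vignette).

Compare detection geometries:

```r
scan  <- detector_spec(25000, 10e6,  100,   "sequential")   # scanning TCSPC
sheet <- detector_spec(25000, 12000, 80000, "simultaneous") # SPAD array
budget_table(sheet, scan, names = c("light_sheet_spad", "laser_scanning"))
#>                   quantity light_sheet_spad laser_scanning
#> 1        image_pixel_count          2.5e+04        2.5e+04
#> 2             dead_time_ns          8.0e+04        1.0e+02
#> 3       max_pixel_rate_cps          1.2e+04        1.0e+07
#> 4      max_system_rate_cps          3.0e+08        1.0e+07
#> 5 effective_pixel_rate_cps          1.2e+04        4.0e+02
#> 6 speed_advantage_a_over_b          3.0e+01             NA
peak_irradiance_sheet(0.4e-3, 200, 9)
#> [1] 28.29421   # W/cm2 — vs ~640,000 for a 5 mW diffraction-limited spot
```

Despite its far slower per-channel rate, the array's 25,000 parallel TDCs
give it a 30× system count-rate advantage, at orders of magnitude lower
peak irradiance.

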
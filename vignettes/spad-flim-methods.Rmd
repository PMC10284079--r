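---
title: "Methods: SPAD-array light-sheet FLIM processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPAD-array light-sheet FLIM processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadflim)
```

## The measurement and its artifacts

`spadflim` processes time-correlated single photon counting (TCSPC) data
from SPAD array cameras used for NAD(P)H autofluorescence lifetime imaging
on light-sheet microscopes. The emulated device is a 192×128 array with a
time-to-digital converter (TDC) per pixel: at a 50 MHz excitation rate the
20 ns laser period is divided into 486 bins of 41.1 ps, and every detected
photon is recorded as (pixel row, pixel column, TDC code). The TDC itself
spans 4096 codes, more than one period; codes beyond the period are cropped
by default (`histogram_from_stream()`), with folding modulo the period
available as an option. How the vendor software maps the full TDC range onto
the period is not documented publicly; cropping is our documented choice and
affects only the small fraction of events beyond bin 485.

Three sensor artifacts must be corrected before lifetime fitting:

* **Dark counts.** Each pixel fires spontaneously at its own dark count rate
  (DCR; median 34 counts/s for this device class, with a heavy-tailed
  distribution). Dark counts are uncorrelated with the laser sync, so they
  add a *uniform* offset across the time axis. `estimate_dcr_map()`
  estimates the per-bin offset from the last 2 ns of each pixel's decay,
  where fluorescence has decayed away, and converts it to a rate via
  `rate = offset_per_bin * n_bins / integration_time`. The offset is later
  held fixed in the fit rather than floated — with only ~500–3000 photons
  per pixel, a free offset trades against the long lifetime component.
* **Timing skew.** Per-pixel TDC chains disagree on time zero by up to ~60
  bins (~2.5 ns) across the array. `estimate_skew_map()` finds each pixel's
  integer lag as the arg-max of the Pearson-normalized circular
  cross-correlation against a reference decay; mean subtraction makes the
  estimate insensitive to the pixel's dark offset (the normalization
  convention is not fixed by common practice; Pearson is ours). Ties break
  toward the smallest |lag|, constant pixels are flagged degenerate.
  `apply_skew_correction()` undoes the lag with a circular shift, which
  conserves per-pixel counts exactly and is idempotent: re-estimating on
  corrected data returns all-zero lags.
* **Screamer and dead pixels.** ~15% of pixels have pathologically high DCR
  ("screamers") and a few never fire. No public criterion exists for the
  screamer cut, so `detect_bad_pixels()` uses a configurable DCR quantile
  (default: flag the top 15%, matching the device class) plus a total-count
  floor for dead pixels. Bad pixels are excluded from reference
  construction, spatial binning and fitting, and carry `NA` sentinels in all
  maps.

### How much signal does skew estimation need?

The lag estimate extracts timing from the sharpest feature of the decay —
its rise edge. Measured recovery rates of injected integer lags (1000
Monte-Carlo replicates, this package's simulator): a pulse-shaped
calibration decay (an IRF acquisition) reaches 99.7% exact recovery at 1000
counts/pixel, an NAD(P)H-like biexponential needs ~3000–4000 counts for 99%,
and a smooth mono-exponential at 2.5 ns is still at ~60% at 1000 counts —
and this is information-limited, not estimator-limited: a
variance-stabilized cross-correlation and a Poisson matched filter perform
the same. Practical consequence: calibrate skew from a bright standard or an
IRF acquisition, not from dim sample data.

## The decay model and the fitter

Fluorescence decays are modeled as a biexponential,
$I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}$ with
$\alpha_1 + \alpha_2 = 1$, where for NAD(P)H the short component
($\tau_1$, typically 0.3–0.5 ns) tracks the free pool and the long
component ($\tau_2$, 2–3 ns) the protein-bound pool. The summary statistic
is the amplitude-weighted mean lifetime
$\tau_m = \alpha_1\tau_1 + \alpha_2\tau_2$.

`model_decay()` implements the periodic reconvolution forward model. At a
finite laser period $T_p$ the tails of previous pulses wrap around; for an
exponential the wrapped kernel has the closed geometric form
$e^{-t/\tau} / (1 - e^{-T_p/\tau})$ on one period, so we use that analytic
kernel instead of convolving several periods — exact for exponentials and
cheaper. The discretized, unit-sum kernel is circularly convolved (FFT) with
the unit-sum instrument response function (IRF), scaled by the photon
amplitude and added to the fixed dark offset. By construction
`sum(model - offset) == amplitude` for every parameter choice — flux
conservation is structural, not numerical.

The IRF (380 ps FWHM for this device class) either comes from a measured
acquisition (`measure_irf()`: aggregate ok-pixel decay, tail offset
subtracted, clipped, normalized) or from a Gaussian model
(`gaussian_irf()`). The IRF position `t0` is taken from calibration; a small
free global shift is deliberately *not* fitted by default. When data and IRF
acquisition are skew-corrected with the same lag map, their time origins are
consistent by construction, which is why `calibrate_sensor()` prefers a
measured IRF acquisition.

`fit_pixel()` minimizes weighted squared residuals with Levenberg–Marquardt
(`minpack.lm::nls.lm`), bounds $\tau \in [0.05, 10]$ ns,
$\alpha_1 \in [0, 1]$, and enforces $\tau_1 \le \tau_2$ by a post-fit swap
to remove label switching. Initialization: biexponential fits start at
typical NAD(P)H values ($\alpha_1 = 0.7$, $\tau_1 = 0.4$, $\tau_2 = 2.5$
ns); mono-exponential fits start from a log-linear regression on the
post-peak decay.

### Residual weighting

TCSPC noise is Poisson, so unweighted least squares over-weights the bright
peak. The textbook fix — weights $1/\max(y, 1)$ from the *observed* counts —
is strongly biased at the count levels of this application: in our
simulations at 3000 photons/pixel it biases $\tau_m$ by −26% (the many
low-count tail bins that fluctuate to 0 or 1 get enormous weight), and
weights recomputed from the model *inside* the optimizer bias +45% (the
optimizer inflates the model where that lowers the weight). The default is
therefore iteratively reweighted least squares: an unweighted pass, then two
passes with weights $1/\max(\hat{m}, 0.5)$ frozen from the previous pass's
fitted model. Measured at the 3000-photon condition: bias +0.8%, SD 4.8%,
reduced $\chi^2$ 0.99. The reported `chi2_reduced` always uses
Poisson-variance weighting from the final model. `weights = "none"` selects
plain least squares.

### The image chain

`fit_image()` runs the standard per-frame chain: photon threshold on the
raw per-pixel signal (default 500 photons *before* binning — totals are
unchanged by the circular shift, so ordering against skew correction is
immaterial), skew correction, spatial binning (`b = 1`, i.e. 3×3 sums with
bad pixels excluded and edges clipped), then per-pixel fits with the
per-pixel dark offset summed over the same binning neighborhood. Per-pixel
intensity is the integrated decay minus the dark contribution.

## Fusion and per-cell statistics

The companion CMOS camera images the same field at twice the SPAD grid per
axis (4× pixels; any integer ratio is supported). `upscale_lifetime()`
interpolates the parameter maps bilinearly to the fine grid and returns the
normalized intensity as a *display weight*: weighting modulates brightness
only — parameter values are never altered by intensity. Cell masks come from
a binary threshold on a labeled channel (e.g. mCherry), 8-connected
components, minimum size 4 pixels (small immune cells at 10×); the threshold
is sample-specific and must be configured. `mask_to_spad_grid()` maps fine
masks to SPAD pixels by fractional coverage (≥ 0.5 by default, majority
label), and `masked_stats()` summarizes fitted pixels per label. CMOS/SPAD
registration is assumed to be a fixed crop-and-scale set optically; no
automatic registration is attempted.

## Throughput and light-dose budgets

The budget module compares detection geometries analytically. A laser
scanning microscope with one timing channel saturates at the channel rate
(~10⁷ cps), giving an *effective* per-image-pixel rate of only ~400 cps over
~25,000 pixels; an array with per-pixel TDCs saturates at
`n_pixels × per_pixel_rate` (~3×10⁸ cps), a 30× system-rate advantage that
scales with pixel count. Irradiance conventions are explicit because
reported numbers depend on them: focused spots use a top-hat convention
(`P/(πr²)`; 5 mW over a 1 µm spot ≈ 6.4×10⁵ W/cm²), light sheets use the
Gaussian peak `2P/(π w₀ · width)` with the waist thickness read as the full
1/e² thickness (0.4 mW over 200 µm × 9 µm ≈ 28 W/cm²); both conventions are
selectable. Dose is irradiance × time. The two-photon dose reported for
comparable systems (~940 J/cm²) is not reproducible from the printed
spot/FOV/dwell parameters under any single convention we tried, so the
package does not compute it; users may apply their own convention.

## The simulator

`sim_config()` defaults *are* the emulated study conditions: 192×128
pixels, 41.1 ps bins, 50 MHz, 380 ps FWHM Gaussian IRF, 10 s integration,
log-normal DCR with median 34 cps (the distribution family is our choice —
only the median is documented for the device class; `sdlog = 0.7` gives a
realistic heavy tail), a smooth left-to-right skew gradient up to 60 bins
with ±2-bin per-pixel jitter, 15% screamers at 100× DCR, and 0.5% dead
pixels. Detection efficiency (13% fill factor, 34% photon detection
probability) is absorbed into the photon budget rather than modeled
geometrically. Photon statistics are per-bin Poisson on the expected curves;
dead-time/pile-up is not modeled because at ≤300 cps per pixel the losses
are negligible. Phantoms are elliptical cells with per-cell parameters drawn
from NAD(P)H literature ranges (α₁ ∈ [0.6, 0.85], τ₁ ∈ [0.3, 0.5] ns,
τ₂ ∈ [2.0, 3.0] ns), 3000 expected photons per cell pixel over the
integration, on a dim biexponential background. Time courses emulate a
cyanide-type perturbation: α₁ ramps up (so τ_m falls) and intensity ramps up
linearly from frame 0; lifetimes of the pools themselves stay fixed, which
matches the biochemical interpretation (the free/bound *ratio* changes).

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: optical shadowing/streak artifacts in the
illumination path, afterpulsing and optical crosstalk between SPAD pixels,
TDC differential nonlinearity beyond a single per-pixel offset,
sample motion, and out-of-focus background. Recovery results on phantoms
are upper bounds on real-data performance.

## Problem sizes and numerical choices

Test and validation runs use sensors from 8×8 to 48×48 pixels with the full
486-bin axis, and the full 192×128 sensor for the dark-acquisition DCR
check; these sizes were chosen so the whole suite exercises every chain at
interactive timescales while keeping Monte-Carlo error well below the
tolerances being asserted. Other numerical choices: lag search bounded at
±75 bins (covers the observed ~60 with margin); FWHM measured with linear
interpolation between bins; sub-bin IRF widths degrade to a single-bin
impulse with a warning; empty masks, all-dark frames, constant decays and
missing files raise typed errors rather than propagating NaN. The
time-course trend test regresses the *per-frame mean over masked fitted
pixels* against time (simple regression; F with (1, n−2) df equals the
squared slope t-statistic); published per-frame F values from live-cell
experiments depend on an undocumented choice of response variable, so they
are not comparison targets. A constant response is reported as F = 0,
p = 1; an exactly linear one as F = ∞, p = 0.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
out <- tempfile("spadflim-run-")
cfg <- pipeline_config(
  out_dir = out, seed = 1,
  sim = list(rows = 48, cols = 48, n_cells = 5, photons_per_pixel = 3000,
             n_frames = 6, frame_interval_min = 3),
  model = "bi", b = 1, min_photons = 500, K = 2, mask_threshold = 100)
res <- run_pipeline(cfg)
res$trends     # per-response slope, F, p over the time course
res$cell_stats # per-cell tau_m / alpha1 / intensity per frame
```

The same stages are available individually (`simulate_histogram()`,
`calibrate_sensor()`, `fit_image()`, `upscale_lifetime()`,
`masked_stats()`, `linear_trend_test()`), and a thin command-line wrapper
(`inst/scripts/spadflim`) exposes `run`, `simulate`, `budget` and `trend`
subcommands.

## Known limitations

Monochrome exponential mixtures only (no phasor analysis, no
triple-exponential or global fits, least squares rather than MLE); no cell
tracking across frames; segmentation is a global threshold plus connected
components; registration is fixed crop-and-scale; calibration assumes the
sensor state (DCR, skew, bad pixels) is stable over the session.
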
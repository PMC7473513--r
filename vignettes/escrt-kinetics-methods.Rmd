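---
title: "Methods: quantifying ESCRT recruitment kinetics at budding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ESCRT recruitment kinetics at budding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

During HIV budding, Gag self-assembles into virus-like particles (VLPs)
at the plasma membrane and recruits the ESCRT machinery — the adaptor
ALIX, the ESCRT-III filament subunit CHMP4b, and the AAA-ATPase VPS4 —
for a brief window of roughly a minute. High-speed TIRF microscopy
(200 ms/frame, 300 frames) resolves this recruitment as
diffraction-limited spots whose integrated fluorescence is proportional
to the number of labeled molecules at the site. Because Gag VLPs barely
move over one minute, the Gag reference channel is imaged only at the
start and end of the record, and the intervening frames are devoted to
two ESCRT channels.

The recruitment profile at a budding site has three phases:

1. **Phase I — assembly.** Sigmoidal recruitment of all factors over
   ~10 s.
2. **Phase II — plateau / early-factor disassembly.** ALIX or CHMP4b
   departs while the VPS4 platform stays at its plateau.
3. **Phase III — late-factor disassembly.** VPS4 departs after a
   retention time of ~15 s.

This package turns that picture into a reproducible pipeline: spot
detection, aperture photometry, cohort normalization, Boltzmann kinetic
fitting, phase segmentation, phenotype classification and
condition-level comparison — with a synthetic movie generator encoding
the same kinetic model, so every stage is validated against ground
truth.

## Kinetic model

All rising and falling segments use the Boltzmann growth equation

$$I(t) = A_1 + \frac{A_2 - A_1}{1 + e^{-(t - t_0)/dx}},$$

with lower/upper asymptotes $A_1, A_2$ (a.u.), midpoint $t_0$ (s) and
width $dx$ (s). Two derived quantities matter:

* **rate** $= (A_2 - A_1) / (4\,dx)$, the maximum slope (a.u./s). The
  source description names the Boltzmann fit but not the rate formula;
  the maximum slope is the only scale-correct single-number slope of a
  sigmoid, and its central region is the "linear" disassembly regime.
* **total assembly time** $T_a = \ln(81)\,dx$, the 10%–90% rise time.

A full event is realized as a smooth sigmoid pulse,
$I(t) = A_1 + (A_2 - A_1)\,\sigma_r(t)\,\sigma_f(t)$, the product of a
rising and a falling sigmoid. The falling midpoint is placed so that
the interval between the rise reaching 90% of its range and the fall
dropping below 90% equals the retention time $\tau$ exactly; this makes
the generator's $\tau$ and the estimator's definition
($\tau = [t_{0d} - \ln(9) dx_d] - [t_{0a} + \ln(9) dx_a]$) coincide by
construction. "Locked" traces (ATP depletion) drop the falling factor.

## The synthetic world

The generator's defaults are the stated acquisition and cohort
conditions, not free dials:

| parameter | default | origin |
|---|---|---|
| frame interval | 0.2 s (5 s for ATP modes) | acquisition protocol |
| frames | 300 (120 for ATP modes) | one-minute record |
| plateau $A_2$ | trunc-N(4900, 1300) a.u. | reported WT maxima |
| depleted $A_2$ | trunc-N(9900, 3300) a.u. | reported ATP-depleted maxima |
| late-channel retention $\tau$ | trunc-N(15, 8) on [0, 30] s | reported retention |
| total assembly time $T_a$ | trunc-N(10, 4) s | reported rise time |
| late/early rise-time ratio | trunc-N(1.6, 0.3) | "assembles almost twice slower" |
| major-phenotype onset gap | trunc-N(10, 2) s | "nearly 10 more seconds" |
| phenotype mixture | 80/20 delayed vs co-disassembly | reported fractions |
| camera | gain 1 e-/a.u., read SD 10 a.u./px, background 100 a.u./px | assumption (no published camera statistics) |
| PSF sigma | 1.3 px | typical TIRF PSF at 60x |

Reported "±" values are interpreted as population SDs (not stated in
the source); draws are truncated normals, truncated at physical bounds.
The retention truncation [0, 30] s is symmetric about 15 s, so it does
not bias the cohort mean; 30 s is half the record, the longest
retention whose disassembly still fits inside it. The published
assembly/disassembly rates in a.u./s are *not* used as generator
inputs: they are mutually inconsistent with the published amplitudes
and rise times (they imply ~50x shallower slopes), and the text's
"twice slower" relation contradicts its own printed rate values, so the
generator anchors on amplitudes, times and fractions and lets rates
follow from the model.

Construction of a dual-channel event: the late channel's retention is
drawn directly (it is the headline quantity); for the major phenotype
the late-minus-early disassembly-onset *gap* is drawn (~10 s) and the
early channel's retention derived from it, clamped at zero; for the
minor phenotype the gap is exactly zero. This guarantees the class
structure the classifier is asked to recover without encoding the
classifier's threshold into the generator.

What the generator does **not** emulate: lateral motion or z-drift,
photobleaching (plateau constancy over a minute implies it is
negligible), chromatic misregistration, cytosolic background structure,
overlapping/clustered VLPs, and membrane scission itself. A green test
therefore establishes correctness of the estimators under the stated
kinetic model and camera statistics — not robustness to every artifact
of live-cell data.

## Estimation pipeline

**Detection.** Difference-of-Gaussians (sigmas $\sigma$ and
$1.6\sigma$), strict 8-neighbour maxima, threshold at
`threshold_snr` × MAD of the response, centroids by intensity-weighted
center of mass in a $(2\lceil 3\sigma\rceil + 1)^2$ window. Sites are
built by greedy nearest-neighbour matching of the start/end Gag
detections (ties broken lexicographically; displacement ≤ 2 px by
default — the source reports "limited movement" without a tolerance).

**Photometry.** Aperture radius 4 px, annulus 6–9 px, median background,
membership by pixel-center distance. The aperture sum is divided by the
encircled energy of the integrated Gaussian over the actual aperture
pixel set, so traces estimate total spot amplitude; noise-free
round-trip error is < 0.1%.

**Normalization.** One scale factor per cohort,
$s = 10000 / \overline{\max_i}$, where $\max_i$ is each trace's maximum
after 3-frame median smoothing (robust to single-frame spikes; the same
definition is used to verify the post-condition, which therefore holds
to machine precision). The grouping of the published normalization is
unstated; one scale per (channel-set, condition) cohort is used, and
cross-condition comparisons must share a scale (pass `scale =` to
`normalize_traces()` / `pipeline_config()`), otherwise the WT vs
ATP-depleted fold change would be silently cancelled —
`compare_conditions()` refuses mixed scales.

**Segmentation.** On the 5-frame median-smoothed trace, plateau = mean
of the top decile; phase I ends at the first 90% crossing; phase II
ends at the last above-90% time before a sustained (≥ 5 frames)
decline; no sustained decline ⇒ censored ("locked"). The event gate
compares the smoothed maximum against baseline + 5 noise SDs, with the
noise SD taken from first differences of the raw trace — a lower-decile
MAD (the literal reading) underestimates noise enough to fail its own
"noise-only trace ⇒ no event" requirement.

**Fitting.** Bounded nonlinear least squares (`nls`, port; `optim`
L-BFGS-B fallback for degenerate starts). Windows come from the
segmentation with a 2 s overlap into the plateau, capped at half the
plateau duration: without the cap, short-retention events put
disassembly samples inside the assembly window and the single-sigmoid
model is mis-specified. Width starts come from the 25%/75% crossing
separation. Fits with $R^2 < 0.5$ are flagged "poor" (parameters still
reported); port's spurious "false convergence" on zero-residual
noise-free data is not treated as failure. Reported phase boundaries
are the *fitted* 90% crossings, so retention equals
`t_II_end − t_I_end` identically.

**Classification.** Delay $\Delta\tau$ = late minus early fitted
disassembly onset; major phenotype if $\Delta\tau > 5$ s, minor if
$|\Delta\tau| \le 5$ s, locked if both channels censored. The 5 s
threshold is the midpoint between the reported ~10 s delay and zero,
well above the ~1 s onset-estimation noise. Kinetic summaries use the
major phenotype only by default (`major_only = FALSE` to include all
classified events), mirroring the source's focus.

**Comparison.** Fold change of mean normalized maxima with a seeded
bootstrap 95% interval (2000 resamples); the source reports only
mean ± SD, so the interval is this package's addition.

## Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes an explicit seed and
  restores the caller's RNG state; identical (config, seed) gives
  byte-identical traces, TIFFs and CSVs.
* Coordinates are 0-based (row, col); frame $k$ is at $t = k\,\Delta t$.
* Spots are rendered over a ±6σ window (truncation error < 1e-6 of the
  amplitude); events must sit ≥ 3σ from the border, and spots closer
  than 4σ void the photometry contract (warning).
* Negative expected photon counts clamp to zero with a warning;
  negative retention estimates clip to zero with a warning.
* Constant traces/windows: no-event status or "poor" fit, never an
  uncaught error.
* The TIFF codec is a deliberate in-package implementation of the
  baseline uncompressed 16-bit grayscale subset (no TIFF package is
  available in the deployment environment); it is round-trip tested,
  including values above the signed 16-bit range.

## Known limitations

* Short retentions (≲ 5 s) make the per-segment sigmoid parameters
  fundamentally less identifiable — the phases overlap in the signal
  itself. Cohort means are unaffected (bias ≪ 1 frame-time), but
  per-event parameters for such tail events carry larger errors, and
  the noise-free 0.1% fidelity check is run on a well-separated
  parameter grid for exactly this reason.
* The ATP-repletion mode (release at a switch time, late channel
  lagging by 5 s) is modeled but the published description is
  qualitative; its defaults are plausible rather than anchored.
* No absolute molecule counting: intensities stay in normalized a.u.;
  converting to subunit numbers needs calibration data this study does
  not provide.
* Classification depends on both channels fitting cleanly; events with
  a poor fit in either channel are counted as unclassifiable rather
  than guessed.
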
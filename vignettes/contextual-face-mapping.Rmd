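---
title: "Mapping contextual tuning of face-selective neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping contextual tuning of face-selective neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemap)
```

## The scientific problem

Face-selective neurons in inferotemporal cortex are classically characterised
with isolated images flashed inside their receptive fields (RFs). A different
picture emerges when large natural scenes are swept across the RF: such
neurons respond not only where a face is, but where a face *ought to be* —
for instance above a body whose face is occluded. Demonstrating this requires
a chain of analyses: grid-registered spatial response maps built from spike
trains, 2D-Gaussian receptive-field estimation, region-conditioned PSTHs with
bin-wise FDR-corrected paired tests and latency estimation, composite
body-orientation preference maps, and representational similarity analysis
(RSA) of category images with permutation nulls.

`facemap` implements that full chain as a reusable, tested pipeline. Because
the recordings that motivate it are not publicly deposited, the package
includes a first-class synthetic module — parametric labelled scenes and an
inhomogeneous-Poisson simulator of contextually tuned face cells — so every
analysis can be validated end-to-end by injecting known effects and checking
that the pipeline recovers them. All results the package reports are
recover-what-was-injected studies on synthetic data; none are re-estimates of
the original recordings.

## Coordinate conventions

One convention is used everywhere:

* visual degrees; fixation at the origin; x rightward, y upward;
* *image* coordinates are degrees relative to the image centre;
* a grid position `g` is the offset of the image centre from fixation;
* rasters store row 1 at the top (y decreasing with row index).

The single most error-prone step is map registration: a presentation at grid
position `g` places image coordinate `c = r − g` over an RF centred at `r`.
`build_scene_response_map()` assigns the windowed rate of that presentation
to coordinate `c`; a delta-responding channel must reconstruct its driving
coordinate exactly, with no mirror or sign error, and the test suite checks
this against the deterministic rate model at several off-centre coordinates.

## Scenes

Scenes are parametric labelled regions (ellipses or polygons) on a 16°×16°
canvas over a brown-noise (1/f² power spectrum) background, not photographs:
the analyses consume only the *relational* structure — a face-shaped region,
a body below it, an occluder over it — which the seven archetype generators
preserve (intact, masked, occluded, face-swapped, face-variants × body,
body orientations, upright/inverted). Each body region carries an
`implied_face` anchor, the point where a face ought to be given the body's
position and orientation, and an `implied_feet` anchor. Faces are drawn with
a 1.5° footprint radius so that even the coarser 2°-spacing presentation
grid always samples at least one node inside a face-shaped region (the
nearest grid node is at most √2 ≈ 1.41° away). Orientation-set bodies are
centred in the image, as in isolated-body stimulus sets on a uniform
background; this also lets per-orientation maps be averaged across
exemplars. Rendering (`render_image()`) is only needed by the RSA pixel
layer and for inspection; the analyses run on region geometry.

## The face-cell model

Each simulated channel is a face cell with

* a 2D Gaussian spatial sensitivity profile, width `rf_sigma_deg`
  (default 1°, giving the 1–3° activating regions typical of these sites),
  centred within ~2° of fixation;
* additive drives with type-specific latencies and gains:

| drive | anchor | default gain (Hz) | default latency (ms) |
|---|---|---|---|
| eyes | eye region centre | 20 | 70 |
| face | face region centre | 40 | 95 |
| implied face (context) | body's `implied_face` | 16 | 130 |
| feet (context) | body's `implied_feet` | 6 | 130 |

The contextual gain defaults to 0.4 of the face gain; its true magnitude
relative to the face response is not known quantitatively, so it is an
exposed free parameter. The 35 ms context delay emulates responses to
occluded faces being ~30–40 ms slower than to intact faces. Face-shaped
noise patches and outlines carry `facelike_scale` (default 0.3) of the face
gain — they retain face shape cues and drive responses above baseline even
without a body. PL-area cells lead ML by 15 ms.

The instantaneous rate is
`baseline + Σ_d gain_d · scale_d · exp(−‖a_d + g − r‖² / 2σ²) · k(t − λ_d)`,
truncated at zero, with spikes drawn as an inhomogeneous Poisson process on
a 1 ms lattice (no refractoriness — all downstream statistics are windowed
means, insensitive to spike-interval structure).

**Response kernel.** `k` is an attack–sustain–release envelope: exponential
rise (τ = 10 ms) to a unit plateau held for the 100 ms stimulus ON period,
exponential release (τ = 40 ms) after offset. A brief transient kernel (a
bare alpha function) was considered and rejected: real IT responses are
sustained for the stimulus duration, the published PSTHs are sustained, and
a ~60 ms transient under the 150 ms analysis windows would make every
windowed statistic average mostly empty bins. The envelope keeps the three
properties the model is specified by: the rate at the kernel peak equals
baseline + gain, the half-max crossing of the trial-averaged rate sits
within the rise time of the configured latency, and evoked counts are linear
in gain.

**Ceiling rule.** A body's implied-face drive is suppressed whenever an
intact face region covers the anchor (`ceiling_rule = TRUE`): bodies
facilitate only when the presence of a face is ambiguous. This makes the
face-above-body vs face-alone contrast exactly null in the model — a
testable zero. **Inversion.** Inverted configurations attenuate contextual
gain by `inversion_attenuation` (default 0.5) for ambiguous stimuli; for
intact faces the upright/inverted difference is confined to the kernel-rise
period, emulating the brief inversion effect for real faces.

## Analysis stages and their numerical choices

**RF mapping.** Probe responses are the mean rate over 80–250 ms after
onset minus the baseline rate over the first 30 ms. The baseline window
closes before the earliest latency, so the baseline does not depend on probe
position; `probe_response_grid()` therefore pools the baseline estimate
across presentations by default (same estimand, far less variance;
`pool_baseline = FALSE` restores strictly per-position subtraction). The 2D
Gaussian (independent σx/σy by default, a shared-σ option) is fitted by
Levenberg–Marquardt on log-σ with multi-start at the grid argmax, making
the noiseless round trip exact to ~1e-6; missing positions are excluded from
the loss, not imputed; flat grids raise a named degenerate-fit error.
"Visually responsive" is operationalised as evoked > baseline at z ≥ 2
across probe trials (the criterion itself is not stated in the source
literature; the threshold is exposed).

**Scene maps.** Windowed mean rates (default 100–250 ms; the slower-latency
profile uses 150–300 ms) registered at `c = r − g`, repetitions averaged;
attribution uses the RF-centre point sample. Analysis windows may overlap
the next presentation's epoch; no correction is applied, matching the
source protocol — at a 300 ms stimulus-onset asynchrony the preceding
response has decayed to numerical zero inside the window. Bilinear
interpolation preserves node values exactly and never extrapolates;
display scaling clips at the 0.5/99.5 percentiles of the dense map (the
percentiles are computed on the interpolated rendering, matching how such
maps are displayed; a constant map collapses to mid-scale). Temporal maps
use half-open, onset-aligned 40 ms bins on the integer millisecond grid.

**Composite orientation maps.** At each grid point the orientation with the
maximal response wins (ties to the first listed orientation); points where
no orientation exceeds baseline are masked. Under finite sampling the
unmasking decision takes a maximum over the eight orientation maps, so the
operational threshold is baseline + z·SE with z the one-sided normal
quantile Bonferroni-corrected across orientations at α = 0.01 per point
(expected falsely unmasked points well below one per composite); with
SE = 0 the rule reduces to the exact at-or-below-baseline mask.

**Region statistics.** A presentation contributes to a region's PSTH iff
the image coordinate over the RF centre lies inside the region; traces are
averaged within image, then summarised across images; Gaussian smoothing
(20 ms support, σ = 5 ms) is applied last. Paired two-sided t-tests run per
1 ms bin across images, BH-FDR corrected at q = 0.05; significant windows
are maximal runs of rejected bins and the reported onset latency is the
start of the first run of ≥ 5 consecutive bins (a minimum run length is not
stated in the source; 5 ms is the exposed default). The per-bin tests are
run on the smoothed traces — smoothing is shared by both conditions and
trades bin-wise independence for power, which is how such displays are
evaluated. Wilcoxon signed-rank verification uses the exact distribution
for n ≤ 25 (dynamic programming over the rank-sum distribution, valid under
ties) and the normal approximation above.

**Latency differences.** The FDR-window onset measures when a difference
becomes *detectable*, which systematically lags more for weaker effects —
consistent with published context-response onsets trailing intact-face
onsets by more than the underlying response delay. To recover an injected
latency *difference*, `half_max_latency()` uses the amplitude-invariant
half-max crossing of the mean difference trace; the latency-recovery study
reports both. That study also sets the eye gain to zero: an eye drive at
70 ms inside the face footprint would otherwise (correctly) dominate the
face-region onset and the recovered quantity would no longer be the
injected face-vs-context difference.

**RSA.** Features are z-scored per unit across images (zero-variance units
dropped, count recorded); similarity is Spearman by default (Pearson and
negative squared Euclidean as alternatives); within-category means exclude
self-pairs. MDS is classical (Torgerson) scaling of the squared Euclidean
distances — deterministic, matching the stated distance input; a
stress-minimising alternative was considered and not used. The label-shuffle
null holds face labels fixed and permutes non-face labels (2500 permutations
at full scale); the weight-shuffle null permutes each layer's weights in
place — preserving the weight distribution exactly while destroying learned
structure — and re-extracts features (500 permutations). The extractor is a
plug-in interface: the pixel layer, seeded random projections, and tiny
ReLU networks cover all tests; a large pretrained network can be plugged in
but no test depends on downloaded weights.

## What the generator emulates — and what it does not

Emulated: Poisson-like spiking around a shared baseline; small central
Gaussian RFs; face-evoked responses at ~95 ms and eye-specific responses at
~70 ms; contextual implied-face responses ~35 ms slower and weaker, with a
weaker feet drive; the ceiling rule; inversion attenuation; PL-before-ML
timing; the presentation protocol (100 ms ON / 200 ms OFF, three images per
trial, every image at every grid position 5–10 times, 17×17/1° and 9×9/2°
profiles).

Not emulated: eye movements and fixational scatter; adaptation and
refractoriness; correlated noise across channels; stimulus-feature
selectivity beyond the labelled regions (no texture or identity tuning);
reward artifacts; spike sorting and waveform variability. Passing tests
therefore show that the *analysis chain* is correct and calibrated under the
stated response model — not that the model captures every property of real
recordings.

## Problem sizes

The recovery studies use: 50 probe sessions (9×9 grid at 1°, 10 reps) for
RF recovery; 20 repetitions and 10 seeds for map fidelity; 10 images × 10
reps × 8 channels for latency recovery; 50 sessions of 8 images × 81
positions × 5 reps × 8 channels per contrast; 8 exemplars × 8 orientations
× 5 reps × 28 channels (the size of a visually responsive array) for the
composite; 200 exchangeable-null experiments; 500 calibration runs of 500
permutations for the RSA null. These sizes make each study a few seconds to
a few minutes on one core while keeping every criterion's sampling error
well inside its margin.

## Known limitations

* Scenes are geometric surrogates; nothing constrains photometric realism.
* The contextual gain fraction (0.4) and feet gain are free parameters; the
  recovery studies hold under moderate variation but no claim is made about
  their physiological values.
* The FDR engine tests bins marginally; run-level error over smoothed,
  correlated bins is only bounded empirically (the exchangeable-null study).
* Population maps average raw rates across channels (channels are combined
  to improve signal to noise); per-channel normalisation is not applied.
* Confidence bands and paired tests treat images as the replication unit;
  an across-channel alternative is not implemented.
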
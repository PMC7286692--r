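# facemap

Grid-registered response maps and contextual tuning analysis for
face-selective neurons.

Face-selective neurons in inferotemporal cortex respond to more than faces:
when a large natural scene is swept across their receptive field (RF), they
also fire for the parts of the image where a face *ought* to be — above a
body whose face is occluded, masked, or replaced. `facemap` is an R package
for the analysis chain behind that finding, aimed at visual
neurophysiologists who work with chronic-array spike data and grid-based
scene presentation:

* **Scene response maps.** A scene shown at grid position `g` (image-centre
  offset from fixation) places image coordinate `c = r − g` over an RF
  centred at `r`; averaging windowed firing rates per position and indexing
  them by `c` yields a map of which image parts drive each site, with
  bilinear interpolation and 0.5–99.5 percentile display scaling.
* **RF estimation.** Probe-grid responses (mean rate over 80–250 ms minus
  the first 30 ms) fitted with a 2D Gaussian
  `off + A·exp(−Δx²/2σx² − Δy²/2σy²)` by Levenberg–Marquardt; population RF
  as the across-channel mean; category selectivity via the index
  `(r₁ − r₂)/(r₁ + r₂)`.
* **Region statistics.** Region-conditioned PSTHs (Gaussian-smoothed over a
  20 ms window), paired two-sided t-tests per 1 ms bin across images with
  Benjamini–Hochberg FDR at q = 0.05, significant-window extraction,
  onset latencies, amplitude-invariant half-max latency differences, and
  exact Wilcoxon signed-rank verification.
* **Composite orientation maps.** For bodies at eight orientations, the
  best orientation per grid point, masked at or below baseline — the
  prediction being that the winning orientation places the implied face
  over the RF.
* **RSA.** Spearman/Pearson/Euclidean similarity of z-scored features,
  within/between-category summaries, classical MDS, label-shuffle and
  weight-shuffle (untrained-network) permutation nulls behind a pluggable
  feature-extractor interface.
* **Synthetic module.** Parametric labelled scenes (seven stimulus-set
  archetypes on a 16°×16° brown-noise canvas) and an inhomogeneous-Poisson
  simulator of contextually tuned face cells — eye, face, implied-face and
  feet drives with distinct latencies, a ceiling rule, inversion
  attenuation — so the whole chain is validated by injecting known effects
  and recovering them. No recordings are required anywhere.

## Worked example

Map an array, then ask where an occluded-face scene drives it:

```r
library(facemap)
arr <- array_model(n_channels = 8, center_deg = c(0.5, 0.5), seed = 1)

# 1. receptive-field mapping from a 9x9 probe grid
probe <- simulate_probe_session(arr, grid_shape = 9, spacing_deg = 1,
                                reps = 10, seed = 2)
pop <- population_rf(lapply(1:8, function(ch)
  probe_response_grid(probe$spikes, probe$protocol, ch)))
fit <- fit_rf_gaussian(pop)

# 2. scene session: 8 occluded-face scenes over a 9x9, 2-degree grid
scenes <- make_scene_set("occluded", 8, seed = 3)
protocol <- make_protocol(9, 2, fit$centroid_deg, scenes, reps = 5, seed = 4)
spikes <- simulate_session(arr, protocol, scenes, seed = 5)
m <- build_scene_response_map(spikes, protocol, "occluded_1", fit$centroid_deg)

# 3. occluded-face region vs the rest of the image, bin-wise FDR
a <- region_traces(spikes, protocol, scenes,
                   region_selector(label = "occluder"), fit$centroid_deg)
b <- region_traces(spikes, protocol, scenes,
                   region_selector(label = c("occluder", "body")),
                   fit$centroid_deg, complement = TRUE)
sig <- binwise_paired_tests(smooth_psth(a), smooth_psth(b))
```

This prints (seeds as above):

```
population RF: centre (0.51, 0.45) deg, sigma (1.03, 1.03) deg, R2 = 0.98
occluded_1: map peak 12.8 Hz at image coordinate (-2, 4); implied-face anchor (-1.99, 3.23)
occluded-face vs non-face: first significant window 136-271 ms (q = 0.05, FDR)
```

Reading it: the fitted population RF matches the simulated array (centre
(0.5, 0.5), σ = 1°). The response map of a scene with *no visible face*
peaks at the image coordinate of the body's implied-face anchor — the
neuron fires when the place where the face ought to be lies over its RF —
and the occluded-face region is significantly stronger than the rest of the
image from ~136 ms, about 35 ms later than an intact face would be, because
the contextual drive is injected at 130 ms versus 95 ms for faces.

The numbered scripts under `analysis/` walk the full study: stimuli, RF
mapping, response maps, region statistics, orientation composites, RSA,
and the end-to-end pipeline (`run_pipeline()`), each writing its tables
under `results/`. The methods vignette
(`vignettes/contextual-face-mapping.Rmd`) documents the model, parameter
defaults, and every numerical choice.

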
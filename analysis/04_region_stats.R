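#!/usr/bin/env Rscript
# Region-conditioned PSTH statistics: the injected context delay, the three
# session-level contrasts (occluded-face, object-above-body, face-above-body
# ceiling) and the type-I calibration of the bin-wise FDR engine.
# Writes results/latency.csv and results/contrasts.csv.

suppressPackageStartupMessages(library(facemap))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

lat <- experiment_context_latency(n_images = 10, reps = 10, n_channels = 8,
                                  seed = seed)
utils::write.csv(data.frame(
  quantity = c("half_max_face_ms", "half_max_context_ms", "shift_ms",
               "fdr_onset_face_ms", "fdr_onset_context_ms"),
  value = c(lat$latency_face_ms, lat$latency_context_ms, lat$shift_ms,
            lat$fdr_onset_face_ms, lat$fdr_onset_context_ms)),
  "results/latency.csv", row.names = FALSE)
cat(sprintf("Context delay: occluded-face responses rise %.0f ms after intact-face responses (injected 35 ms; FDR onsets %.0f vs %.0f ms).\n",
            lat$shift_ms, lat$fdr_onset_context_ms, lat$fdr_onset_face_ms))

n_sessions <- 20
rows <- lapply(c("occluded", "swap", "ceiling"), function(ct) {
  res <- experiment_contrast(ct, n_sessions = n_sessions, seed = seed + 1L)
  data.frame(contrast = ct, n_sessions = n_sessions,
             fraction_significant = res$fraction_significant)
})
contrasts <- do.call(rbind, rows)
utils::write.csv(contrasts, "results/contrasts.csv", row.names = FALSE)
print(contrasts, row.names = FALSE)
cat("Occluded faces and objects above bodies drive significant windows;\n")
cat("faces above bodies do not (ceiling rule), matching the injected model.\n")

null <- experiment_type1(n_runs = 200, seed = seed + 2L)
cat(sprintf("Exchangeable null: any FDR-rejected bin in %.1f%% of 200 runs (run-level bound 10%%).\n",
            100 * null$fraction_any_rejection))
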
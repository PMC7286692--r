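#!/usr/bin/env Rscript
# Generate the seven stimulus-set archetypes and a presentation protocol,
# and record their structure. Writes results/scenes_*.json and
# results/stimulus_summary.csv.

suppressPackageStartupMessages(library(facemap))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

sets <- list(
  intact = make_scene_set("intact", 8, seed = seed),
  masked = make_scene_set("masked", 8, seed = seed + 1L),
  occluded = make_scene_set("occluded", 8, seed = seed + 2L),
  face_swapped = make_scene_set("face_swapped", 8, seed = seed + 3L),
  face_variants_x_body = make_scene_set("face_variants_x_body", 7,
                                        seed = seed + 4L),
  body_orientations = make_scene_set("body_orientations", 8,
                                     seed = seed + 5L),
  upright_inverted = make_scene_set("upright_inverted", 7, seed = seed + 6L))

summary <- do.call(rbind, lapply(names(sets), function(nm) {
  scenes <- sets[[nm]]
  data.frame(image_set = nm, n_scenes = length(scenes),
             n_with_face = sum(vapply(scenes, function(s)
               any(vapply(s$regions, function(r) r$label == "face", TRUE)),
               TRUE)),
             n_with_body = sum(vapply(scenes, function(s)
               any(vapply(s$regions, function(r) r$label == "body", TRUE)),
               TRUE)))
}))
utils::write.csv(summary, "results/stimulus_summary.csv", row.names = FALSE)
write_scenes_json(sets$occluded, "results/scenes_occluded.json")
write_scenes_json(sets$body_orientations, "results/scenes_orientations.json")

protocol <- make_protocol(9, 2, c(0.5, 0.5), sets$occluded, reps = 5,
                          seed = seed)
utils::write.csv(protocol$events, "results/protocol_events.csv",
                 row.names = FALSE)

cat("Stimulus sets generated:\n")
print(summary, row.names = FALSE)
cat(sprintf("Protocol: %d presentations in %d trials (%d scenes x 81 positions x 5 reps).\n",
            nrow(protocol$events), max(protocol$events$trial),
            length(sets$occluded)))
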
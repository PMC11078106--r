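#!/usr/bin/env Rscript
# Build the synthetic study scene: one ON smooth monostratified RGC with
# four planted bipolar-input hotspots, plus three ON parasol RGCs whose
# somas sit inside the smooth cell's dendritic field (left, centre, right).
# Writes the CSV/JSON dataset plus the planted ground truth.

suppressPackageStartupMessages(library(hotspotter))

SEED <- 20240901L
out_dir <- "results/scene"

scene <- generate_paired_scene(
  smooth_skeleton_config(SEED),
  list(parasol_skeleton_config(SEED + 1L, soma_center = c(-45, 0)),
       parasol_skeleton_config(SEED + 2L, soma_center = c(0, 0)),
       parasol_skeleton_config(SEED + 3L, soma_center = c(45, 0))),
  smooth_synapse_model(SEED + 4L))

write_dataset(scene, out_dir)

message("cells:     ", nrow(scene$cells))
message("nodes:     ", nrow(scene$nodes))
message("synapses:  ", nrow(scene$synapses))
for (cid in scene$cells$cell_id) {
  syn <- subset_synapses(scene, cid)
  message(sprintf("  %-10s %4d synapses (%d ribbon / %d conventional)",
                  cid, nrow(syn), sum(syn$kind == "ribbon"),
                  sum(syn$kind == "conventional")))
}
message("scene written to ", out_dir,
        " (truth.json records the planted hotspots)")
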
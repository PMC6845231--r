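#!/usr/bin/env Rscript
# Step 1 — generate the synthetic recordings used by the downstream steps:
# a flash movie with motion + noise (for registration), a noiseless flash
# movie (for metric recovery), and an edge movie (for direction tuning).
# Movies (binary TIFF) go to scratch/; small summaries to results/.

suppressPackageStartupMessages(library(calcifly))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

p_flash <- build_flash_protocol(7, 5, pre_gray_s = 5)
set.seed(seed)
cells <- lapply(1:8, function(i) {
  cell_spec(i, center_px = c(sample(15:50, 1), sample(15:50, 1)),
            radius_px = 4, f_baseline = 30, tau_rise_s = 0.05)
})
cfg <- movie_config(64, 64, frame_rate_hz = 12, photon_gain = 100,
                    read_noise_sd = 2, motion_walk_sd = 1, max_shift_px = 8,
                    seed = seed)
sim <- suppressWarnings(render_movie(cells, p_flash, config = cfg))
write_movie_tiff(sim$movie, "scratch/sim/flash_moving.tif")
write_mask_tiff(sim$rois, "scratch/sim/flash_rois.tif")
write_protocol_json(p_flash, "scratch/sim/flash_protocol.json")
write_config_yaml(cfg, "scratch/sim/flash_config.yaml")
write.csv(data.frame(frame = seq_len(nrow(sim$truth$shifts)),
                     sim$truth$shifts),
          "scratch/sim/flash_true_shifts.csv", row.names = FALSE)

cat(sprintf("flash movie: %d frames, %d cells, walk sd %.1f px (max |shift| %d)\n",
            n_frames(sim$movie), length(cells), cfg$motion_walk_sd,
            max(abs(sim$truth$shifts))))

p_edge <- build_edge_protocol(20, reps = 3, gray_s = 2, seed = seed)
cat(sprintf("edge protocol: %d edge epochs of %.1f s (%d directions x 2 contrasts x 3 reps)\n",
            sum(p_edge$epochs$kind == "edge"),
            unique(p_edge$epochs$duration_s[p_edge$epochs$kind == "edge"]),
            8))
write_protocol_json(p_edge, "scratch/sim/edge_protocol.json")

summary <- data.frame(
  artifact = c("flash_moving.tif", "edge_protocol.json"),
  frames = c(n_frames(sim$movie), NA),
  duration_s = c(protocol_duration(p_flash), protocol_duration(p_edge)))
write.csv(summary, "results/01_simulated_artifacts.csv", row.names = FALSE)
cat("wrote results/01_simulated_artifacts.csv\n")
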
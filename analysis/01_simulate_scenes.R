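#!/usr/bin/env Rscript
# Simulate a ground-truthed reference scene: a cell migrating on a 20-um
# stripe with contact-site puncta that are stationary in the lab frame,
# denser and larger towards the back. Writes the rendered movie and ground
# truth under scratch/ (binary/large) and a scene summary under results/.

suppressPackageStartupMessages(library(mcsgrad))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
out <- "scratch/analysis/01_simulate"

cfg <- scene_config(seed = 101)
print(cfg)
pc <- pipeline_config(scene = cfg)
run_pipeline(pc, mode = "simulate", out_dir = out)

truth <- utils::read.csv(file.path(out, "truth_puncta.csv"))
obs <- utils::read.csv(file.path(out, "truth_puncta_observations.csv"))
lab_spread <- tapply(obs$x, obs$id, function(x) diff(range(x)))

summary_tbl <- data.frame(
  n_frames = cfg$n_frames,
  frame_interval_s = cfg$frame_interval,
  pixel_size_um = cfg$pixel_size,
  cell_speed_um_min = cfg$cell_speed,
  n_puncta = nrow(truth),
  n_observations = nrow(obs),
  censored_fraction = mean(is.na(truth$death_frame)),
  max_lab_frame_drift_px = max(lab_spread),
  mean_mass_front_half = mean(obs$mass[obs$p < 0.5]),
  mean_mass_back_half = mean(obs$mass[obs$p >= 0.5]))
utils::write.csv(summary_tbl, "results/analysis/01_scene_summary.csv",
                 row.names = FALSE)

cat(sprintf(
  "Simulated %d puncta over %d frames; every track is lab-frame stationary
(max drift %.1g px). Mean mass back/front = %.2f, reflecting the position-
dependent growth field. Movie and tables in %s.\n",
  nrow(truth), cfg$n_frames, max(lab_spread),
  summary_tbl$mean_mass_back_half / summary_tbl$mean_mass_front_half, out))
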
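#!/usr/bin/env Rscript
# Contact-site puncta dynamics: detection with the 40%-band threshold,
# nearest-neighbour tracking, lifetimes versus mass, and the retrograde
# flow field of lab-frame-stationary contacts under a migrating cell.

suppressPackageStartupMessages(library(mcsgrad))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
out <- "scratch/analysis/03_puncta"

cfg <- scene_config(seed = 303, puncta_birth_rate_front = 0.002,
                    puncta_birth_rate_back = 0.006,
                    puncta_growth_rate_front = 0, puncta_growth_rate_back = 0,
                    death_rate_scale = 0.2, mass_stability_threshold = Inf,
                    initial_mass = 2)
pc <- pipeline_config(scene = cfg)
run_pipeline(pc, mode = "puncta", out_dir = out)

flow <- utils::read.csv(file.path(out, "puncta_flow_summary.csv"))
tracks <- utils::read.csv(file.path(out, "puncta_tracks.csv"))

## lifetime-versus-mass at scale, from the death model directly
lt <- experiment_lifetime_mass(n = 1000, seed = 303)
utils::write.csv(lt$dependent$binned,
                 "results/analysis/03_lifetime_vs_mass.csv",
                 row.names = FALSE)
utils::write.csv(
  data.frame(n_tracks = nrow(tracks),
             censored = sum(tracks$censored),
             mean_lab_speed_um_min = flow$mean_lab_speed_um_min,
             mean_cell_frame_speed_um_min = flow$mean_cell_frame_speed_um_min,
             cell_speed_um_min = flow$cell_speed_um_min,
             lifetime_mass_spearman_rho = lt$dependent$spearman_rho),
  "results/analysis/03_puncta_summary.csv", row.names = FALSE)

cat(sprintf(
  "Tracked %d puncta (%d censored). Lab-frame speed %.3f um/min versus
cell-frame %.2f um/min at cell speed %.2f: contacts are stationary on the
substrate and flow rearward in the cell frame. Binned lifetimes rise with
birth mass (Spearman rho %.2f).\n",
  nrow(tracks), sum(tracks$censored), flow$mean_lab_speed_um_min,
  flow$mean_cell_frame_speed_um_min, flow$cell_speed_um_min,
  lt$dependent$spearman_rho))
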
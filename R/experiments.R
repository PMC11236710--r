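#' Simulation experiments at the package's study conditions
#'
#' Each function runs one of the package's benchmark experiments on
#' synthetic scenes with known ground truth and returns the measured
#' quantities together with the configured truth. The conditions (scene
#' geometry, rates, noise) are fixed choices documented in the methods
#' vignette; only the seed and replication counts are free.
#'
#' @name experiments
NULL

#' Gradient-recovery experiment
#'
#' Simulates stationary cells with a configured back:front puncta density
#' ratio and recovers the inverse front/back half ratio (`1 / ratio50`) of
#' the reporter-to-PM-marker gradient profile through the full segmentation
#' and binning pipeline. Stationary scenes are used because only there does
#' the steady-state density ratio equal the configured birth-rate ratio
#' exactly (a migrating cell depletes its freshly swept front).
#'
#' @param g configured back:front density ratio.
#' @param n_cells number of simulated cells.
#' @param noise `FALSE` for noise-free rendering, `TRUE` for the default
#'   camera-noise model.
#' @param seed base seed; cell `i` uses `seed + i`.
#' @return List with `recovered` (mean of per-cell `1/ratio50`),
#'   `per_cell`, and `g`.
#' @export
experiment_gradient_recovery <- function(g, n_cells = 20, noise = TRUE,
                                         seed = 1L) {
  vals <- vapply(seq_len(n_cells), function(i) {
    cfg <- scene_config(
      seed = seed + i, cell_speed = 0,
      puncta_birth_rate_front = 0.03, puncta_birth_rate_back = 0.03 * g,
      puncta_growth_rate_front = 0, puncta_growth_rate_back = 0,
      mass_stability_threshold = Inf, initial_mass_sdlog = 0.3,
      noise_gaussian_sd = if (noise) 10 else 0,
      noise_poisson_gain = if (noise) 1 else 0)
    sc <- simulate_scene(cfg)
    gr <- movie_gradient_analysis(sc$movie, pipeline_config(scene = cfg))
    1 / gr$steepness$ratio50
  }, numeric(1))
  list(recovered = mean(vals), per_cell = vals, g = g)
}

#' Retrograde-flow experiment
#'
#' Simulates migrating cells with lab-frame-stationary puncta at sparse
#' density, runs detection/tracking, and summarizes the mean lab-frame and
#' cell-frame punctum speeds against the configured cell speed.
#'
#' @param n_cells number of simulated cells.
#' @param seed base seed.
#' @return List with per-cell summaries and the across-cell means
#'   `mean_lab_speed`, `mean_cell_frame_speed`, `cell_speed` (um/min).
#' @export
experiment_flow <- function(n_cells = 4, seed = 1L) {
  rows <- lapply(seq_len(n_cells), function(i) {
    cfg <- scene_config(
      seed = seed + i,
      puncta_birth_rate_front = 0.002, puncta_birth_rate_back = 0.006,
      puncta_growth_rate_front = 0, puncta_growth_rate_back = 0,
      death_rate_scale = 0.2, mass_stability_threshold = Inf,
      initial_mass = 2)
    sc <- simulate_scene(cfg)
    pa <- movie_puncta_analysis(sc$movie, pipeline_config(scene = cfg))
    cbind(pa$flow$summary, configured_speed = cfg$cell_speed)
  })
  per_cell <- do.call(rbind, rows)
  list(per_cell = per_cell,
       mean_lab_speed = mean(per_cell$mean_lab_speed_um_min),
       mean_cell_frame_speed = mean(per_cell$mean_cell_frame_speed_um_min),
       cell_speed = mean(per_cell$configured_speed))
}

#' Growth-rate slope-recovery experiment
#'
#' Simulates migrating cells whose puncta are born near the front and grow
#' three times faster in the back half, detects and tracks them, and fits
#' the front/back growth-rate slopes with [growth_rate_curve()].
#'
#' @param n_cells number of simulated cells.
#' @param seed base seed.
#' @param growth_ratio configured back/front growth-rate ratio.
#' @return The [growth_rate_curve()] result plus `configured_ratio`.
#' @export
experiment_growth_slopes <- function(n_cells = 14, seed = 1L,
                                     growth_ratio = 3) {
  gobs <- NULL
  for (i in seq_len(n_cells)) {
    cfg <- scene_config(
      seed = seed + i, image_shape = c(64L, 280L), n_frames = 24L,
      puncta_birth_rate_front = 0.006, puncta_birth_rate_back = 0,
      puncta_growth_rate_front = 0.15,
      puncta_growth_rate_back = 0.15 * growth_ratio,
      death_rate_scale = 0, initial_mass_sdlog = 0.25)
    sc <- simulate_scene(cfg)
    pa <- movie_puncta_analysis(sc$movie, pipeline_config(scene = cfg))
    ob <- pa$tracking$observations
    ob$track_id <- ob$track_id + i * 1e7
    gobs <- rbind(gobs, ob[, c("track_id", "p", "ratio")])
  }
  out <- growth_rate_curve(gobs)
  out$configured_ratio <- growth_ratio
  out
}

#' Lifetime-versus-mass experiment
#'
#' Monte Carlo of the punctum death model: under the mass-dependent hazard,
#' binned mean lifetime rises with birth mass; under a constant hazard the
#' profile is flat.
#'
#' @param n tracks per arm.
#' @param seed seed.
#' @return List with `dependent` / `flat` arms, each holding the track
#'   table, the [lifetime_vs_mass()] binning, the Spearman test
#'   (dependent arm) and the 99% slope confidence interval (flat arm).
#' @export
experiment_lifetime_mass <- function(n = 1000, seed = 1L) {
  set.seed(seed)
  mass0 <- exp(stats::rnorm(n, 0, 0.6))
  dep <- simulate_lifetimes(n, mass0 = mass0, growth_rate = 0,
                            death_rate_scale = 1.2,
                            mass_stability_threshold = 3,
                            dt_min = 1 / 3, max_frames = 400L)
  unc <- !dep$censored
  ct <- stats::cor.test(dep$mass_birth[unc], dep$lifetime_s[unc],
                        method = "spearman", exact = FALSE)
  flat <- simulate_lifetimes(n, mass0 = mass0, growth_rate = 0,
                             death_rate_scale = 0.5,
                             mass_stability_threshold = Inf,
                             dt_min = 1 / 3, max_frames = 2000L)
  bf <- lifetime_vs_mass(flat, breaks = 8, mass_col = "mass_birth")
  fit <- stats::lm(mean_lifetime_s ~ mass_mid, data = bf, weights = bf$n)
  ci <- stats::confint(fit, "mass_mid", level = 0.99)
  list(dependent = list(tracks = dep,
                        binned = lifetime_vs_mass(dep, breaks = 8,
                                                  mass_col = "mass_birth"),
                        spearman_rho = unname(ct$estimate),
                        spearman_p = ct$p.value),
       flat = list(tracks = flat, binned = bf,
                   slope_ci99 = c(ci[1], ci[2])))
}

#' Puncta-tracking fidelity experiment
#'
#' Links the ground-truth observation tables of sparse 20-second-interval
#' scenes and scores the fraction of ground-truth tracks recovered whole
#' (one recovered track holding exactly that punctum's observations).
#'
#' @param n_scenes number of scenes pooled.
#' @param seed base seed.
#' @return List with `recovery` (pooled fraction), `per_scene`, and
#'   `peak_density` (puncta per pixel^2, highest frame across scenes).
#' @export
experiment_tracking_fidelity <- function(n_scenes = 6, seed = 1L) {
  whole <- total <- 0
  dens <- numeric(0)
  per_scene <- numeric(n_scenes)
  for (i in seq_len(n_scenes)) {
    cfg <- scene_config(seed = seed + i, frame_interval = 20, n_frames = 15L,
                        puncta_birth_rate_front = 0.01,
                        puncta_birth_rate_back = 0.03,
                        puncta_growth_rate_front = 0,
                        puncta_growth_rate_back = 0,
                        death_rate_scale = 0.3,
                        mass_stability_threshold = Inf)
    geom <- simulate_cell_geometry(cfg)
    truth <- simulate_puncta(cfg, geom)
    o <- truth$observations
    dens <- c(dens, max(table(o$frame)) / sum(geom$masks[[1]]))
    obs <- data.frame(frame = o$frame, y = o$y, x = o$x, mass = o$mass * 2000)
    linked <- link_observations(obs, max_disp = 3, mass_weight = 1)
    key <- paste(linked$frame, round(linked$y, 6), round(linked$x, 6))
    gtkey <- paste(o$frame, round(o$y, 6), round(o$x, 6))
    linked$gt_id <- o$id[match(key, gtkey)]
    tab <- table(linked$gt_id, linked$track_id)
    ok <- 0L
    for (g in rownames(tab)) {
      tid <- colnames(tab)[tab[g, ] > 0]
      if (length(tid) == 1 && sum(tab[, tid] > 0) == 1) ok <- ok + 1L
    }
    whole <- whole + ok
    total <- total + nrow(truth$puncta)
    per_scene[i] <- ok / nrow(truth$puncta)
  }
  list(recovery = whole / total, per_scene = per_scene,
       peak_density = max(dens))
}

#' Two-cell crossing identity experiment
#'
#' Constructed trajectories of two cells crossing mid-movie with a 2:1 mass
#' contrast; identities are preserved when each mass class maps to a single
#' recovered track.
#'
#' @param n_seeds number of replicate noise seeds.
#' @param seed base seed.
#' @return List with `preserved_fraction` and `n_seeds`.
#' @export
experiment_crossing <- function(n_seeds = 40, seed = 1L) {
  ok <- 0L
  for (i in seq_len(n_seeds)) {
    set.seed(seed + i)
    fr <- 1:21
    obs <- data.frame(
      frame = rep(fr, 2),
      y = c(30 + stats::rnorm(21, 0, 0.3), 32 + stats::rnorm(21, 0, 0.3)),
      x = c(20 + 4 * (fr - 1), 100 - 4 * (fr - 1)) + stats::rnorm(42, 0, 0.3),
      mass = c(stats::rnorm(21, 2000, 60), stats::rnorm(21, 1000, 30)))
    lk <- link_observations(obs, max_disp = 10, mass_weight = 1)
    heavy <- unique(lk$track_id[lk$mass > 1500])
    light <- unique(lk$track_id[lk$mass <= 1500])
    if (length(heavy) == 1 && length(light) == 1) ok <- ok + 1L
  }
  list(preserved_fraction = ok / n_seeds, n_seeds = n_seeds)
}
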
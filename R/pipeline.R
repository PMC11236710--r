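#' Front-to-back gradient analysis of a movie
#'
#' Runs the 1D stripe-migration analysis chain on one movie: per frame,
#' segments the cell from the PM channel, finds the front tip, forms the
#' offset-subtracted reporter-to-denominator ratio image, and bins it into
#' front-to-back segments; assembles the kymograph, the time-averaged
#' profile and the polarity-steepness scores, and records the cell
#' centroid track.
#'
#' @param movie an `mcs_movie` array (from [render_movie()] or
#'   [read_movie()]).
#' @param config a [pipeline_config()].
#' @param denominator channel role used as ratio denominator, `"pm"`
#'   (default) or `"er"`.
#' @param use_ring bin over the peripheral ring instead of the full mask
#'   (used for peripheral signals such as phosphotyrosine).
#' @param numerator channel role of the numerator (default `"mapper"`).
#' @return List with `profiles` (per frame), `kymograph`, `mean_profile`,
#'   `steepness`, `masks`, `axes`, `cell_track` (data frame
#'   `frame, y, x, mass`), and `skipped` frames where no cell was found.
#' @export
movie_gradient_analysis <- function(movie, config, denominator = "pm",
                                    use_ring = FALSE, numerator = "mapper") {
  cm <- config$channel_map
  offset <- config$scene$camera_offset
  ps <- attr(movie, "pixel_size") %||% config$scene$pixel_size
  n_frames <- dim(movie)[1]
  profiles <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  axes <- vector("list", n_frames)
  track <- list()
  prev_axis <- NULL
  for (t in seq_len(n_frames)) {
    pm_img <- matrix(movie[t, cm$pm, , ], dim(movie)[3], dim(movie)[4])
    num_img <- pmax(matrix(movie[t, cm[[numerator]], , ],
                           dim(movie)[3], dim(movie)[4]) - offset, 0)
    den_img <- pmax(matrix(movie[t, cm[[denominator]], , ],
                           dim(movie)[3], dim(movie)[4]) - offset, 0)
    cells <- segment_cell_pm(pm_img, pixel_size = ps)
    if (length(cells) == 0) next
    cell <- cells[[which.max(vapply(cells, `[[`, numeric(1), "area"))]]
    axis <- find_front(cell$mask, previous_axis = prev_axis)
    prev_axis <- axis$axis
    bin_mask <- if (use_ring) {
      ring_mask(cell$mask, width_um = config$ring_width_um, pixel_size = ps)
    } else cell$mask
    ratio <- ratio_image(num_img, den_img, mask = bin_mask,
                         floor = config$denom_floor)
    profiles[[t]] <- bin_profile(ratio, bin_mask, axis,
                                 n_bins = config$n_bins,
                                 normalize = config$normalize_profiles)
    masks[[t]] <- cell$mask
    axes[[t]] <- axis
    track[[length(track) + 1L]] <- data.frame(
      frame = t, y = cell$centroid["y"], x = cell$centroid["x"],
      mass = cell$mass)
  }
  skipped <- which(vapply(profiles, is.null, logical(1)))
  if (length(skipped) == n_frames) stop("no cell found in any frame")
  kymo <- assemble_kymograph(profiles)
  cell_track <- do.call(rbind, track)
  rownames(cell_track) <- NULL
  list(profiles = profiles, kymograph = kymo, mean_profile = kymo$mean,
       steepness = steepness(kymo$mean), masks = masks, axes = axes,
       cell_track = cell_track, skipped = skipped)
}

#' Puncta detection, tracking and flow analysis of a movie
#'
#' Detects contact-reporter puncta in every frame (threshold calibrated at
#' the 40% front band), links them into tracks, and computes lifetimes and
#' the lab-frame / cell-frame flow field against the cell centroid track.
#'
#' @param movie an `mcs_movie` array.
#' @param config a [pipeline_config()].
#' @param gradients optional result of [movie_gradient_analysis()] for the
#'   same movie (recomputed when missing; it supplies masks, axes and the
#'   cell track).
#' @return List with `detections`, `tracking` (see [link_puncta()]),
#'   `flow` (see [flow_field()]) and `lifetime_mass`
#'   (see [lifetime_vs_mass()]).
#' @export
movie_puncta_analysis <- function(movie, config, gradients = NULL) {
  if (is.null(gradients)) {
    gradients <- movie_gradient_analysis(movie, config)
  }
  cm <- config$channel_map
  offset <- config$scene$camera_offset
  ps <- attr(movie, "pixel_size") %||% config$scene$pixel_size
  fi <- attr(movie, "frame_interval") %||% config$scene$frame_interval
  n_frames <- dim(movie)[1]
  dets <- list()
  for (t in seq_len(n_frames)) {
    if (is.null(gradients$masks[[t]])) next
    mapper <- matrix(movie[t, cm$mapper, , ], dim(movie)[3], dim(movie)[4])
    caax <- pmax(matrix(movie[t, cm$pm, , ],
                        dim(movie)[3], dim(movie)[4]) - offset, 0)
    d <- detect_puncta(mapper, gradients$masks[[t]], gradients$axes[[t]],
                       tophat_radius_px = config$tophat_radius_px,
                       threshold_band = config$threshold_band,
                       min_area = config$min_punctum_area,
                       pixel_size = ps, ratio_denom = caax)
    if (nrow(d) > 0) {
      d$frame <- t
      dets[[length(dets) + 1L]] <- d
    }
  }
  detections <- if (length(dets) > 0) do.call(rbind, dets) else
    data.frame(frame = integer(0), y = numeric(0), x = numeric(0),
               area = numeric(0), mean_intensity = numeric(0),
               mass = numeric(0), p = numeric(0))
  if (nrow(detections) == 0) {
    return(list(detections = detections, tracking = NULL, flow = NULL,
                lifetime_mass = NULL))
  }
  tracking <- link_puncta(detections, n_frames = n_frames,
                          frame_interval = fi,
                          max_disp_px = config$puncta_max_disp_px,
                          mass_weight = config$mass_weight)
  flow <- flow_field(tracking$observations, gradients$cell_track,
                     pixel_size = ps, frame_interval = fi,
                     cell_masks = gradients$masks)
  lt <- if (any(!tracking$tracks$censored)) {
    lifetime_vs_mass(tracking$tracks)
  } else NULL
  list(detections = detections, tracking = tracking, flow = flow,
       lifetime_mass = lt)
}

#' Run the full pipeline on a configuration
#'
#' Chains the stages the way the imaging study is analysed: `simulate`
#' renders a ground-truthed synthetic movie; `stripes1d` segments and
#' tracks the 1D migrating cell; `gradients` adds profiles, kymographs and
#' steepness; `puncta` adds puncta detection, tracking, lifetimes and flow;
#' `track2d` segments nuclei and computes speed and MSD; `all` runs
#' everything. Outputs are CSV tables (each carrying the configuration
#' hash), a kymograph PNG and a JSON run report; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param mode one of `simulate`, `track2d`, `stripes1d`, `puncta`,
#'   `gradients`, `all`.
#' @param out_dir output directory (created if needed).
#' @param movie optional movie to analyse; by default the scene is
#'   simulated (modes other than `simulate` require either a movie or a
#'   simulatable scene).
#' @return Invisibly, a list of the stage results and output paths.
#' @export
run_pipeline <- function(config,
                         mode = c("all", "simulate", "track2d", "stripes1d",
                                  "puncta", "gradients"),
                         out_dir, movie = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (mode %in% c("stripes1d", "puncta", "gradients", "all") &&
      !("mapper" %in% names(config$channel_map))) {
    stop("channel map has no 'mapper' channel for mode ", mode)
  }
  if (mode == "track2d" && !isTRUE(config$scene$include_nuclei) &&
      is.null(movie)) {
    stop("track2d needs a nuclear channel: set include_nuclei in the scene")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  set.seed(config$seed)
  results <- list(config_hash = hash)
  counts <- list()
  tbl <- function(df, name) {
    df$config_hash <- rep(hash, nrow(df))
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  scene <- NULL
  if (is.null(movie)) {
    scene <- simulate_scene(config$scene)
    movie <- scene$movie
    if (mode %in% c("simulate", "all")) {
      write_movie(movie, file.path(out_dir, "movie.tif"))
      tbl(scene$truth$puncta, "truth_puncta")
      tbl(scene$truth$observations, "truth_puncta_observations")
      tbl(scene$geometry$centroids, "truth_cell_centroids")
      write_pipeline_config(config, file.path(out_dir, "config.yaml"))
      counts$true_puncta <- nrow(scene$truth$puncta)
    }
    results$scene <- scene
  }
  ps <- attr(movie, "pixel_size")
  fi <- attr(movie, "frame_interval")

  if (mode %in% c("stripes1d", "gradients", "puncta", "all")) {
    grad <- movie_gradient_analysis(movie, config)
    results$gradients <- grad
    tbl(grad$cell_track, "cell_track")
    counts$frames_with_cell <- nrow(grad$cell_track)
    if (mode != "stripes1d") {
      prof <- as.data.frame(t(grad$kymograph$matrix))
      names(prof) <- sprintf("bin%02d", seq_len(config$n_bins))
      prof <- cbind(frame = seq_len(nrow(prof)), prof)
      tbl(prof, "kymograph")
      st <- grad$steepness
      tbl(data.frame(score20 = st$score20, ratio50 = st$ratio50,
                     log2_ratio50 = st$log2_ratio50), "steepness")
      fb <- front_back_summary(grad$mean_profile)
      tbl(data.frame(front20 = fb$front, back20 = fb$back),
          "front_back_summary")
      kymo_png(grad$kymograph, file.path(out_dir, "kymograph.png"), fi)
    }
    if (nrow(grad$cell_track) >= 2) {
      counts$cell_speed_um_min <- compute_speed(grad$cell_track, ps, fi)
    }
  }

  if (mode %in% c("puncta", "all")) {
    pa <- movie_puncta_analysis(movie, config, gradients = results$gradients)
    results$puncta <- pa
    tbl(pa$detections, "puncta_detections")
    counts$puncta_detections <- nrow(pa$detections)
    if (!is.null(pa$tracking)) {
      tbl(pa$tracking$tracks, "puncta_tracks")
      tbl(pa$flow$vectors, "puncta_flow_vectors")
      tbl(pa$flow$summary, "puncta_flow_summary")
      counts$puncta_tracks <- nrow(pa$tracking$tracks)
    }
    if (!is.null(pa$lifetime_mass)) tbl(pa$lifetime_mass, "lifetime_vs_mass")
  }

  if (mode %in% c("track2d", "all") && "NUC" %in% dimnames(movie)[[2]]) {
    obs <- list()
    for (t in seq_len(dim(movie)[1])) {
      nuc <- matrix(movie[t, "NUC", , ], dim(movie)[3], dim(movie)[4])
      det <- segment_nuclei(nuc, pixel_size = ps)
      if (nrow(det) > 0) {
        det$frame <- t
        obs[[length(obs) + 1L]] <- det
      }
    }
    if (length(obs) > 0) {
      nobs <- do.call(rbind, obs)
      max_disp_px <- config$cell_max_disp_um / ps
      tracks <- link_cells(nobs[, c("frame", "y", "x", "mass")],
                           max_disp = max_disp_px,
                           mass_weight = config$mass_weight)
      tbl(tracks, "nuclei_tracks")
      msd <- compute_msd(tracks, ps, fi)
      tbl(msd, "msd")
      results$track2d <- list(tracks = tracks, msd = msd)
      counts$nuclei_tracks <- length(unique(tracks$track_id))
    }
  }

  report <- list(package_version = as.character(utils::packageVersion("mcsgrad")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 mode = mode, seed = config$seed, config_hash = hash,
                 counts = counts)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$report <- report
  invisible(results)
}

# kymograph heatmap: time on x, the 20 front-to-back bins on y
kymo_png <- function(kymo, path, frame_interval) {
  grDevices::png(path, width = 640, height = 360)
  on.exit(grDevices::dev.off())
  mat <- kymo$matrix
  graphics::image(x = seq_len(ncol(mat)) * frame_interval / 60,
                  y = seq_len(nrow(mat)), z = t(mat[rev(seq_len(nrow(mat))), ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (min)", ylab = "front-to-back bin",
                  useRaster = TRUE)
  invisible(path)
}
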
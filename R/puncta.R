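#' Detect contact-reporter puncta in one frame
#'
#' White-top-hat filters the reporter channel (disc structuring element of
#' the stated radius), then computes an Otsu threshold only from filtered
#' pixels whose normalized axial position lies in `threshold_band` (a band
#' around 40% from the cell front). Thresholding at that band keeps the dim
#' front contacts detectable instead of calibrating on the bright back.
#' Connected components above threshold and at least `min_area` pixels are
#' measured on an aperture grown two pixels around each component (nearest
#' component wins contested pixels), which captures the Gaussian tails that
#' fall below the cutoff. Centroids are then polished by iterative
#' fixed-window intensity-weighted refinement, which decouples the position
#' estimate from noise-driven flicker of the aperture boundary.
#'
#' @param mapper reporter channel matrix (raw intensities; any constant
#'   camera offset is removed by the top-hat filter).
#' @param cell_mask logical cell mask.
#' @param axis an [find_front()] axis frame for the same mask.
#' @param tophat_radius_px top-hat disc radius in pixels (default 3).
#' @param threshold_band axial interval used for the threshold (default
#'   `c(0.35, 0.45)`, a symmetric band around 0.40); if it contains no
#'   pixels the whole mask is used, with a warning.
#' @param min_area minimum component area in pixels (default 2).
#' @param noise_floor_k the threshold is never allowed below
#'   `median + noise_floor_k * MAD` of the filtered signal inside the cell
#'   (default 5); this is the "modification" of the Otsu step — when the
#'   calibration band holds few spots, a plain Otsu split lands inside the
#'   camera-noise distribution and floods the frame with false puncta. Zero
#'   for noise-free images (MAD is 0 there, so the floor is inactive).
#' @param pixel_size optional pixel size (um) to report areas in um^2.
#' @param ratio_denom optional denominator channel (e.g. the PM marker);
#'   adds per-punctum `denom_mean` and `ratio` (= mass / denominator mean).
#' @return Data frame, one row per punctum: `frame` (`NA`, for the caller
#'   to fill), `y, x` (intensity-weighted centroid, px), `area` (aperture
#'   px), `area_um2` (if `pixel_size` given), `mean_intensity` (filtered),
#'   `mass` (= mean intensity x area = integrated filtered intensity), `p`
#'   (axial position of the centroid), plus ratio columns when requested.
#' @export
detect_puncta <- function(mapper, cell_mask, axis, tophat_radius_px = 3,
                          threshold_band = c(0.35, 0.45), min_area = 2,
                          noise_floor_k = 5, pixel_size = NULL,
                          ratio_denom = NULL) {
  stopifnot(all(dim(mapper) == dim(cell_mask)))
  # EBImage greyscale morphology assumes the [0, 1] range
  scale <- max(mapper, 1)
  th <- EBImage::whiteTopHat(mapper / scale, ebi_brush(tophat_radius_px))
  th <- as.matrix(th) * scale

  band <- cell_mask & !is.na(axis$p) & axis$p >= threshold_band[1] &
    axis$p <= threshold_band[2]
  if (!any(band)) {
    warning("threshold band contains no pixels; using the whole cell mask")
    band <- cell_mask
  }
  cell_vals <- th[cell_mask]
  noise_floor <- stats::median(cell_vals) + noise_floor_k * stats::mad(cell_vals)
  thr <- max(otsu_threshold(th[band]), noise_floor)
  fg <- cell_mask & th > thr & th > 0
  empty <- data.frame(frame = integer(0), y = numeric(0), x = numeric(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      mass = numeric(0), p = numeric(0))
  if (!any(fg)) return(empty)
  lbl <- EBImage::bwlabel(fg * 1)
  areas <- tabulate(lbl[lbl > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty)
  core <- lbl
  core[!(core %in% keep)] <- 0
  # measurement aperture: cores grown 2 px (Voronoi propagation), clipped
  # to the cell mask
  grow <- ebi_dilate(core > 0, 2L) & cell_mask
  ap <- EBImage::propagate(th, seeds = core, mask = grow * 1)
  ap <- as.matrix(ap)

  rows <- lapply(keep, function(k) {
    idx <- which(ap == k, arr.ind = TRUE)
    w <- th[idx]
    ctr <- weighted_centroid(idx, w)
    ctr <- refine_centroid(th, ctr["y"], ctr["x"],
                           r = tophat_radius_px - 0.5)
    proj <- ((ctr["y"] - axis$front[1]) * axis$axis[1] +
               (ctr["x"] - axis$front[2]) * axis$axis[2]) / axis$length_px
    r <- data.frame(frame = NA_integer_, y = unname(ctr["y"]),
                    x = unname(ctr["x"]), area = nrow(idx),
                    mean_intensity = mean(w), mass = sum(w),
                    p = unname(pmin(pmax(proj, 0), 1)))
    if (!is.null(ratio_denom)) {
      r$denom_mean <- mean(ratio_denom[idx])
      r$ratio <- r$mass / r$denom_mean
    }
    r
  })
  out <- do.call(rbind, rows)
  if (!is.null(pixel_size)) out$area_um2 <- out$area * pixel_size^2
  rownames(out) <- NULL
  out
}

# iterative intensity-weighted centroid in a fixed circular window
# (standard sub-pixel particle-localization polish)
refine_centroid <- function(th, y0, x0, r = 2.5, iters = 3L) {
  ny <- nrow(th); nx <- ncol(th)
  for (i in seq_len(iters)) {
    ylo <- max(1, floor(y0 - r)); yhi <- min(ny, ceiling(y0 + r))
    xlo <- max(1, floor(x0 - r)); xhi <- min(nx, ceiling(x0 + r))
    yy <- ylo:yhi; xx <- xlo:xhi
    W <- th[yy, xx, drop = FALSE]
    W[outer((yy - y0)^2, (xx - x0)^2, "+") > r^2] <- 0
    W[W < 0] <- 0
    if (sum(W) <= 0) break
    y0 <- sum(row(W) * W) / sum(W) + ylo - 1
    x0 <- sum(col(W) * W) / sum(W) + xlo - 1
  }
  c(y = y0, x = x0)
}

#' Link puncta detections into tracks with lifetimes
#'
#' Same nearest-neighbour cost structure as [link_cells()] but with a tight
#' displacement gate, since contacts are near-stationary in the lab frame.
#' Lifetime is the duration from appearance to disappearance or the last
#' frame, inclusive: `(last - first + 1) * frame_interval`. Tracks touching
#' the first or last movie frame are flagged censored.
#'
#' @param detections data frame of per-frame puncta (needs
#'   `frame, y, x, mass`).
#' @param n_frames total number of movie frames (for censoring).
#' @param frame_interval frame interval in seconds.
#' @param max_disp_px linking gate in pixels (default 3).
#' @param mass_weight mass-term weight (default 1).
#' @return List with `observations` (detections plus `track_id`) and
#'   `tracks` (per track: `track_id, first_frame, last_frame, n_obs,
#'   lifetime_s, censored, mass_first, mass_mean, mass_max`).
#' @export
link_puncta <- function(detections, n_frames, frame_interval,
                        max_disp_px = 3, mass_weight = 1) {
  obs <- link_observations(detections, max_disp = max_disp_px,
                           mass_weight = mass_weight)
  by_tr <- split(obs, obs$track_id)
  tracks <- do.call(rbind, lapply(by_tr, function(tr) {
    data.frame(track_id = tr$track_id[1],
               first_frame = min(tr$frame), last_frame = max(tr$frame),
               n_obs = nrow(tr),
               lifetime_s = (max(tr$frame) - min(tr$frame) + 1) * frame_interval,
               censored = min(tr$frame) == 1L || max(tr$frame) == n_frames,
               mass_first = tr$mass[which.min(tr$frame)],
               mass_mean = mean(tr$mass),
               mass_max = max(tr$mass))
  }))
  rownames(tracks) <- NULL
  list(observations = obs, tracks = tracks)
}

#' Mean punctum lifetime per mass bin
#'
#' Censored tracks (alive at the movie boundaries) are excluded from the
#' naive mean and counted separately; the mass used for binning is the mass
#' at first observation by default, which is not confounded by track age
#' (a long-lived punctum has had more time to grow, so binning by mean or
#' final mass would create a lifetime-mass correlation even under a
#' mass-independent hazard).
#'
#' @param tracks track table with `lifetime_s`, `censored` and a mass
#'   column (e.g. from [link_puncta()] or [simulate_lifetimes()]).
#' @param breaks mass bin breaks, or a number of quantile bins (default 8).
#' @param mass_col mass column name (default `"mass_first"`, falling back
#'   to `"mass_birth"` then `"mass"`).
#' @return Data frame per bin: `mass_lo, mass_hi, mass_mid, n,
#'   mean_lifetime_s, median_lifetime_s, n_censored`; empty bins keep
#'   `NA` lifetimes.
#' @export
lifetime_vs_mass <- function(tracks, breaks = 8, mass_col = NULL) {
  if (is.null(mass_col)) {
    mass_col <- intersect(c("mass_first", "mass_birth", "mass"),
                          names(tracks))[1]
  }
  if (is.na(mass_col)) stop("no mass column found")
  m <- tracks[[mass_col]]
  if (length(breaks) == 1) {
    qs <- unique(stats::quantile(m, probs = seq(0, 1, length.out = breaks + 1)))
    if (length(qs) < 2) qs <- range(m) + c(-1e-9, 1e-9)
    breaks <- qs
  }
  breaks[1] <- min(breaks[1], min(m))
  breaks[length(breaks)] <- max(breaks[length(breaks)], max(m))
  bin <- cut(m, breaks, include.lowest = TRUE, labels = FALSE)
  unc <- !tracks$censored
  if (!any(unc)) {
    out <- data.frame(mass_lo = utils::head(breaks, -1),
                      mass_hi = breaks[-1])
    out$mass_mid <- (out$mass_lo + out$mass_hi) / 2
    out$n <- 0L
    out$mean_lifetime_s <- NA_real_
    out$median_lifetime_s <- NA_real_
    out$n_censored <- tabulate(bin, nbins = nrow(out))
    return(out)
  }
  nb <- length(breaks) - 1L
  out <- data.frame(mass_lo = utils::head(breaks, -1), mass_hi = breaks[-1])
  out$mass_mid <- (out$mass_lo + out$mass_hi) / 2
  out$n <- tabulate(bin[unc], nbins = nb)
  out$mean_lifetime_s <- vapply(seq_len(nb), function(k) {
    v <- tracks$lifetime_s[unc & bin == k]
    if (length(v) > 0) mean(v) else NA_real_
  }, numeric(1))
  out$median_lifetime_s <- vapply(seq_len(nb), function(k) {
    v <- tracks$lifetime_s[unc & bin == k]
    if (length(v) > 0) stats::median(v) else NA_real_
  }, numeric(1))
  out$n_censored <- tabulate(bin[!unc], nbins = nb)
  out
}

#' Lab-frame and cell-frame displacement vectors of tracked puncta
#'
#' For every consecutive observation pair of every punctum track, the
#' lab-frame vector is the punctum displacement and the cell-frame vector is
#' that displacement minus the cell centroid displacement over the same
#' frames (the retrograde-flow field). Puncta observed outside the cell mask
#' are excluded and counted.
#'
#' @param punctum_obs tracked punctum observations
#'   (`track_id, frame, y, x`).
#' @param cell_centroids per-frame cell centroids (`frame, y, x`).
#' @param pixel_size pixel size in micrometres.
#' @param frame_interval frame interval in seconds.
#' @param cell_masks optional list of per-frame masks used to exclude
#'   puncta outside the cell.
#' @return List with `vectors` (data frame `track_id, frame0, frame1,
#'   dy_lab, dx_lab, dy_cell, dx_cell` in pixels), `summary` (per-movie
#'   mean lab-frame and cell-frame punctum speeds and the mean cell speed,
#'   um/min, with log2 values), and `n_excluded`.
#' @export
flow_field <- function(punctum_obs, cell_centroids, pixel_size,
                       frame_interval, cell_masks = NULL) {
  obs <- punctum_obs[order(punctum_obs$track_id, punctum_obs$frame), ,
                     drop = FALSE]
  n_excluded <- 0L
  if (!is.null(cell_masks)) {
    inside <- vapply(seq_len(nrow(obs)), function(i) {
      m <- cell_masks[[obs$frame[i]]]
      iy <- pmin(pmax(round(obs$y[i]), 1L), nrow(m))
      ix <- pmin(pmax(round(obs$x[i]), 1L), ncol(m))
      m[iy, ix]
    }, logical(1))
    n_excluded <- sum(!inside)
    obs <- obs[inside, , drop = FALSE]
  }
  cc <- cell_centroids[order(cell_centroids$frame), , drop = FALSE]
  cy <- stats::setNames(cc$y, cc$frame)
  cx <- stats::setNames(cc$x, cc$frame)

  same <- obs$track_id[-1] == obs$track_id[-nrow(obs)] &
    obs$frame[-1] == obs$frame[-nrow(obs)] + 1L
  i0 <- which(c(same, FALSE))
  if (length(i0) == 0) {
    vectors <- data.frame(track_id = integer(0), frame0 = integer(0),
                          frame1 = integer(0), dy_lab = numeric(0),
                          dx_lab = numeric(0), dy_cell = numeric(0),
                          dx_cell = numeric(0))
  } else {
    f0 <- obs$frame[i0]; f1 <- obs$frame[i0 + 1L]
    dy_lab <- obs$y[i0 + 1L] - obs$y[i0]
    dx_lab <- obs$x[i0 + 1L] - obs$x[i0]
    dyc <- cy[as.character(f1)] - cy[as.character(f0)]
    dxc <- cx[as.character(f1)] - cx[as.character(f0)]
    vectors <- data.frame(track_id = obs$track_id[i0], frame0 = f0,
                          frame1 = f1, dy_lab = dy_lab, dx_lab = dx_lab,
                          dy_cell = unname(dy_lab - dyc),
                          dx_cell = unname(dx_lab - dxc))
  }
  to_umin <- pixel_size / (frame_interval / 60)
  lab_speed <- mean(sqrt(vectors$dy_lab^2 + vectors$dx_lab^2)) * to_umin
  cell_frame_speed <- mean(sqrt(vectors$dy_cell^2 + vectors$dx_cell^2)) * to_umin
  cell_speed <- mean(sqrt(diff(cc$y)^2 + diff(cc$x)^2)) * to_umin
  list(vectors = vectors,
       summary = data.frame(
         mean_lab_speed_um_min = lab_speed,
         mean_cell_frame_speed_um_min = cell_frame_speed,
         cell_speed_um_min = cell_speed,
         log2_lab_speed = log2(lab_speed),
         log2_cell_frame_speed = log2(cell_frame_speed)),
       n_excluded = n_excluded)
}
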
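#' Simulate per-frame cell geometry on a stripe
#'
#' Builds one capsule-shaped cell mask per frame, confined to the adhesive
#' stripe and advancing at the configured speed. The front end is a linear
#' cone (sharp tip) and the rear a semicircular cap, so the tip is always the
#' boundary point farthest from the mask centroid and front detection is well
#' posed.
#'
#' @param config a [scene_config()].
#' @return A `cell_geometry` list with elements `masks` (list of logical
#'   Y-by-X matrices, one per frame), `centroids` (data frame `frame, y, x`
#'   in pixels), `front_x` (true tip x per frame, pixels), `length_px`,
#'   `direction`, and the config used.
#' @export
simulate_cell_geometry <- function(config) {
  cfg <- validate_scene_config(config)
  ny <- cfg$image_shape[1]
  nx <- cfg$image_shape[2]
  L <- cfg$cell_length / cfg$pixel_size
  r <- cfg$stripe_width / 2 / cfg$pixel_size
  v_px <- cfg$cell_speed * (cfg$frame_interval / 60) / cfg$pixel_size
  travel <- v_px * (cfg$n_frames - 1L)

  margin <- 2
  xf0 <- cfg$start_front_x
  if (is.null(xf0)) {
    # place so the full run fits in the field of view
    xf0 <- if (cfg$direction < 0) margin + travel + 1 else nx - margin - travel - L
  }

  front_x <- xf0 + cfg$direction * v_px * (seq_len(cfg$n_frames) - 1L)
  rear_x <- front_x - cfg$direction * L
  lo <- pmin(front_x, rear_x)
  hi <- pmax(front_x, rear_x)
  bad <- which(lo < 1 | hi > nx)
  if (length(bad) > 0) {
    stop(sprintf("cell leaves the field of view at frame %d", bad[1]))
  }

  yc <- (ny + 1) / 2
  cone_len <- min(2.5 * r, 0.45 * L)  # sharp front taper
  xs <- seq_len(nx)
  ys <- seq_len(ny)
  dy <- abs(ys - yc)

  masks <- vector("list", cfg$n_frames)
  cent <- matrix(NA_real_, cfg$n_frames, 2)
  for (t in seq_len(cfg$n_frames)) {
    d <- (xs - front_x[t]) * (-cfg$direction)  # distance from tip along the axis
    h <- rep(-1, nx)
    inside <- d >= 0 & d <= L
    hcap <- ifelse(d < cone_len, r * d / cone_len,
                   ifelse(d <= L - r, r, sqrt(pmax(0, r^2 - (d - (L - r))^2))))
    h[inside] <- hcap[inside]
    m <- outer(dy, h, FUN = "<=")
    masks[[t]] <- m
    idx <- which(m, arr.ind = TRUE)
    cent[t, ] <- c(mean(idx[, 1]), mean(idx[, 2]))
  }

  structure(list(
    masks = masks,
    centroids = data.frame(frame = seq_len(cfg$n_frames),
                           y = cent[, 1], x = cent[, 2]),
    front_x = front_x,
    length_px = L,
    direction = cfg$direction,
    config = cfg
  ), class = "cell_geometry")
}

#' True normalized axial coordinate of lab-frame positions
#'
#' Ground-truth counterpart of the axial coordinate estimated by
#' [find_front()]: 0 at the front tip, 1 at the rear, clipped to `[0, 1]`.
#'
#' @param geometry a [simulate_cell_geometry()] result.
#' @param x lab-frame x positions in pixels.
#' @param frame frame index.
#' @return Numeric vector of axial coordinates.
#' @export
true_axial_position <- function(geometry, x, frame) {
  d <- (x - geometry$front_x[frame]) * (-geometry$direction)
  pmin(pmax(d / geometry$length_px, 0), 1)
}
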
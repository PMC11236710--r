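#' Render a multichannel movie from simulated geometry and puncta
#'
#' Channels: `CAAX` (PM marker) is the mask fill plus a brighter one-pixel
#' membrane rim; `SEC61B` (ER marker) is the mask fill excluding a thin
#' lamellipodial margin; `MAPPER` (contact reporter) renders each punctum as
#' an analytically pixel-integrated Gaussian spot whose integrated intensity
#' is proportional to its mass; optional `NUC` is a Gaussian nuclear blob at
#' the cell centroid and optional `PTYR` a phosphotyrosine ramp decreasing
#' from front to back. Poisson shot noise, camera offset and Gaussian read
#' noise are applied last and pixel values are digitized to non-negative
#' integers (16-bit range), so written movies round-trip bit-exactly.
#'
#' @param config a [scene_config()].
#' @param geometry output of [simulate_cell_geometry()].
#' @param puncta output of [simulate_puncta()] (or `NULL` for no spots).
#' @return A numeric array of dimension `(T, C, Y, X)` with integer values,
#'   channel names in `dimnames`, and attributes `pixel_size` (um/px) and
#'   `frame_interval` (s). Class `mcs_movie`.
#' @export
render_movie <- function(config, geometry, puncta = NULL) {
  cfg <- validate_scene_config(config)
  set.seed(cfg$seed + 2L)
  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  channels <- c("CAAX", "SEC61B", "MAPPER",
                if (cfg$include_nuclei) "NUC",
                if (cfg$include_ptyr) "PTYR")
  movie <- array(0, dim = c(cfg$n_frames, length(channels), ny, nx),
                 dimnames = list(NULL, channels, NULL, NULL))
  sigma_px <- cfg$punctum_sigma_um / cfg$pixel_size
  margin_px <- max(1L, round(cfg$sec61_margin_um / cfg$pixel_size))
  obs <- if (is.null(puncta)) NULL else puncta$observations

  for (t in seq_len(cfg$n_frames)) {
    m <- geometry$masks[[t]]
    rim <- m & !ebi_erode(m, 1L)
    caax <- cfg$caax_intensity * m + cfg$caax_rim_bonus * rim
    sec61 <- cfg$sec61_intensity * ebi_erode(m, margin_px)

    mapper <- matrix(0, ny, nx)
    if (!is.null(obs)) {
      o <- obs[obs$frame == t, , drop = FALSE]
      if (nrow(o) > 0) {
        amp <- cfg$mapper_intensity_per_mass * o$mass
        mapper <- add_gaussian_spots(mapper, o$y, o$x, sigma_px, amp)
      }
    }
    movie[t, "CAAX", , ] <- apply_camera_noise(caax, cfg)
    movie[t, "SEC61B", , ] <- apply_camera_noise(sec61, cfg)
    movie[t, "MAPPER", , ] <- apply_camera_noise(mapper, cfg)
    if (cfg$include_nuclei) {
      ctr <- geometry$centroids[t, ]
      nuc <- add_gaussian_spots(matrix(0, ny, nx), ctr$y, ctr$x,
                                cfg$nucleus_sigma_um / cfg$pixel_size,
                                cfg$nucleus_intensity * 2 * pi *
                                  (cfg$nucleus_sigma_um / cfg$pixel_size)^2)
      movie[t, "NUC", , ] <- apply_camera_noise(nuc, cfg)
    }
    if (cfg$include_ptyr) {
      p <- matrix(true_axial_position(geometry, rep(seq_len(nx), each = ny), t),
                  ny, nx)
      ramp <- (cfg$ptyr_front + (cfg$ptyr_back - cfg$ptyr_front) * p) * m
      movie[t, "PTYR", , ] <- apply_camera_noise(ramp, cfg)
    }
  }
  attr(movie, "pixel_size") <- cfg$pixel_size
  attr(movie, "frame_interval") <- cfg$frame_interval
  class(movie) <- c("mcs_movie", class(movie))
  movie
}

#' Add pixel-integrated Gaussian spots to an image
#'
#' Each spot contributes `amplitude * [Phi integrals over the pixel box]`,
#' i.e. the exact integral of an isotropic 2D Gaussian over each pixel, so
#' sub-pixel centroids are rendered without bias and the total added
#' intensity equals `amplitude` up to window truncation (window radius
#' `6 * sigma`). Spots extending past the image border are clipped.
#'
#' @param img numeric matrix to add into.
#' @param y,x spot centres in pixel coordinates (may be fractional).
#' @param sigma_px Gaussian sigma in pixels (scalar or per spot).
#' @param amplitude integrated intensity per spot.
#' @return The image with spots added.
#' @export
add_gaussian_spots <- function(img, y, x, sigma_px, amplitude) {
  ny <- nrow(img); nx <- ncol(img)
  sigma_px <- rep_len(sigma_px, length(y))
  amplitude <- rep_len(amplitude, length(y))
  for (i in seq_along(y)) {
    s <- sigma_px[i]
    w <- ceiling(6 * s)
    ylo <- max(1L, floor(y[i] - w)); yhi <- min(ny, ceiling(y[i] + w))
    xlo <- max(1L, floor(x[i] - w)); xhi <- min(nx, ceiling(x[i] + w))
    if (ylo > yhi || xlo > xhi) next
    yy <- ylo:yhi; xx <- xlo:xhi
    fy <- stats::pnorm(yy + 0.5, y[i], s) - stats::pnorm(yy - 0.5, y[i], s)
    fx <- stats::pnorm(xx + 0.5, x[i], s) - stats::pnorm(xx - 0.5, x[i], s)
    img[yy, xx] <- img[yy, xx] + amplitude[i] * outer(fy, fx)
  }
  img
}

# Poisson shot noise on the signal, then camera offset, Gaussian read noise,
# digitization and clipping to the 16-bit range. With both noise parameters
# zero the output is the rounded signal plus offset, exactly.
apply_camera_noise <- function(signal, cfg) {
  out <- signal
  if (cfg$noise_poisson_gain > 0) {
    out <- stats::rpois(length(signal), pmax(signal, 0) / cfg$noise_poisson_gain) *
      cfg$noise_poisson_gain
    dim(out) <- dim(signal)
  }
  out <- out + cfg$camera_offset
  if (cfg$noise_gaussian_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, cfg$noise_gaussian_sd)
  }
  out <- round(out)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  out
}

#' Simulate a complete ground-truthed scene
#'
#' Convenience wrapper chaining [simulate_cell_geometry()],
#' [simulate_puncta()] and [render_movie()] under the configured seed.
#'
#' @param config a [scene_config()].
#' @return List with `geometry`, `truth` (ground-truth tables) and `movie`.
#' @export
simulate_scene <- function(config) {
  geometry <- simulate_cell_geometry(config)
  truth <- simulate_puncta(config, geometry)
  movie <- render_movie(config, geometry, truth)
  list(geometry = geometry, truth = truth, movie = movie, config = config)
}
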
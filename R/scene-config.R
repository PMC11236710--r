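#' Configuration for a synthetic stripe-migration scene
#'
#' Bundles every parameter of the generative model behind the synthetic
#' time-lapse movies: cell geometry and speed on a micropatterned stripe,
#' the puncta birth/growth/death fields, channel rendering intensities and
#' the camera-noise model. All physical quantities are given in micrometres,
#' seconds and micrometres per minute; pixels are only used internally.
#'
#' The puncta birth-rate field is linear in the normalized front-to-back
#' coordinate `p` and is anchored at the half centres (`p = 0.25` and
#' `p = 0.75`), so `puncta_birth_rate_front` and `puncta_birth_rate_back`
#' are the mean birth rates of the front and back halves of the cell and
#' their quotient is the configured back:front density ratio. Negative
#' interpolated rates are clamped to zero. The mass growth-rate field is
#' piecewise constant by half (`puncta_growth_rate_front` for `p < 0.5`,
#' `puncta_growth_rate_back` for `p >= 0.5`). The death hazard is
#' `death_rate_scale * max(0, 1 - mass / mass_stability_threshold)` per
#' minute, so small contacts are short-lived and contacts above the
#' stability threshold are near-immortal.
#'
#' @param image_shape integer `(Y, X)` image size in pixels.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames.
#' @param stripe_width adhesive stripe width in micrometres; the cell body
#'   fills the stripe width.
#' @param cell_length cell length in micrometres (tip to rear).
#' @param cell_speed migration speed in micrometres per minute.
#' @param direction `-1` (default) migrates towards decreasing x, so the
#'   front is the leftmost tip; `+1` mirrors the scene.
#' @param puncta_birth_rate_front,puncta_birth_rate_back puncta birth rates,
#'   events per square micrometre per minute, mean over the front/back half.
#' @param puncta_growth_rate_front,puncta_growth_rate_back mass growth rates
#'   per minute in the front/back half.
#' @param death_rate_scale death hazard scale, per minute.
#' @param mass_stability_threshold mass above which the death hazard is zero.
#' @param initial_mass,initial_mass_sdlog birth mass log-normal parameters:
#'   median and log-sd.
#' @param punctum_sigma_um rendered Gaussian spot sigma in micrometres.
#' @param caax_intensity,caax_rim_bonus PM channel fill intensity and the
#'   extra intensity of the one-pixel membrane rim.
#' @param sec61_intensity,sec61_margin_um ER channel fill intensity and the
#'   width of the lamellipodial margin excluded from the ER fill.
#' @param mapper_intensity_per_mass integrated contact-reporter intensity per
#'   unit mass.
#' @param nucleus_intensity,nucleus_sigma_um nuclear channel blob amplitude
#'   and sigma (rendered when `include_nuclei`).
#' @param ptyr_front,ptyr_back end-point intensities of the phosphotyrosine
#'   ramp, decreasing from front to back (rendered when `include_ptyr`).
#' @param include_nuclei,include_ptyr render the optional channels.
#' @param camera_offset camera offset in digital numbers, added after noise.
#' @param noise_gaussian_sd Gaussian read-noise sd in digital numbers; 0
#'   disables it.
#' @param noise_poisson_gain Poisson (shot) noise gain; 0 disables it.
#' @param start_front_x optional starting front-tip x position in pixels;
#'   by default placed so the whole run fits in the field of view.
#' @param seed integer seed; a fixed seed makes the whole scene (masks,
#'   ground-truth tables and rendered movie) bit-reproducible.
#'
#' @return An object of class `scene_config` (a validated named list).
#' @export
scene_config <- function(image_shape = c(64L, 220L),
                         pixel_size = 0.4,
                         frame_interval = 120,
                         n_frames = 15L,
                         stripe_width = 20,
                         cell_length = 40,
                         cell_speed = 1,
                         direction = -1L,
                         puncta_birth_rate_front = 0.02,
                         puncta_birth_rate_back = 0.06,
                         puncta_growth_rate_front = 0.2,
                         puncta_growth_rate_back = 0.6,
                         death_rate_scale = 0.5,
                         mass_stability_threshold = 5,
                         initial_mass = 1,
                         initial_mass_sdlog = 0.5,
                         punctum_sigma_um = 0.25,
                         caax_intensity = 400,
                         caax_rim_bonus = 400,
                         sec61_intensity = 300,
                         sec61_margin_um = 1.2,
                         mapper_intensity_per_mass = 2000,
                         nucleus_intensity = 800,
                         nucleus_sigma_um = 2.5,
                         ptyr_front = 600,
                         ptyr_back = 150,
                         include_nuclei = FALSE,
                         include_ptyr = FALSE,
                         camera_offset = 100,
                         noise_gaussian_sd = 10,
                         noise_poisson_gain = 1,
                         start_front_x = NULL,
                         seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    stripe_width = stripe_width,
    cell_length = cell_length,
    cell_speed = cell_speed,
    direction = as.integer(direction),
    puncta_birth_rate_front = puncta_birth_rate_front,
    puncta_birth_rate_back = puncta_birth_rate_back,
    puncta_growth_rate_front = puncta_growth_rate_front,
    puncta_growth_rate_back = puncta_growth_rate_back,
    death_rate_scale = death_rate_scale,
    mass_stability_threshold = mass_stability_threshold,
    initial_mass = initial_mass,
    initial_mass_sdlog = initial_mass_sdlog,
    punctum_sigma_um = punctum_sigma_um,
    caax_intensity = caax_intensity,
    caax_rim_bonus = caax_rim_bonus,
    sec61_intensity = sec61_intensity,
    sec61_margin_um = sec61_margin_um,
    mapper_intensity_per_mass = mapper_intensity_per_mass,
    nucleus_intensity = nucleus_intensity,
    nucleus_sigma_um = nucleus_sigma_um,
    ptyr_front = ptyr_front,
    ptyr_back = ptyr_back,
    include_nuclei = isTRUE(include_nuclei),
    include_ptyr = isTRUE(include_ptyr),
    camera_offset = camera_offset,
    noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_gain = noise_poisson_gain,
    start_front_x = start_front_x,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  stopifnot(
    length(cfg$image_shape) == 2L, all(cfg$image_shape >= 8L),
    cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$n_frames >= 1L,
    cfg$stripe_width > 0, cfg$cell_length > 0, cfg$cell_speed >= 0,
    cfg$direction %in% c(-1L, 1L)
  )
  rates <- c(cfg$puncta_birth_rate_front, cfg$puncta_birth_rate_back,
             cfg$puncta_growth_rate_front, cfg$puncta_growth_rate_back,
             cfg$death_rate_scale)
  if (any(rates < 0)) stop("all birth/growth/death rates must be >= 0")
  if (cfg$mass_stability_threshold <= 0) {
    stop("mass_stability_threshold must be > 0 (use Inf for a constant hazard)")
  }
  if (cfg$cell_length / cfg$pixel_size >= cfg$image_shape[2]) {
    stop("cell_length must be smaller than the image x extent")
  }
  if (cfg$stripe_width / cfg$pixel_size >= cfg$image_shape[1]) {
    stop("stripe_width must be smaller than the image y extent")
  }
  if (any(c(cfg$camera_offset, cfg$noise_gaussian_sd, cfg$noise_poisson_gain) < 0)) {
    stop("noise parameters must be >= 0")
  }
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic stripe-migration scene configuration\n")
  cat(sprintf("  field: %d x %d px at %.3g um/px, %d frames every %g s\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              x$n_frames, x$frame_interval))
  cat(sprintf("  cell: %g um long on a %g um stripe, %g um/min towards %s\n",
              x$cell_length, x$stripe_width, x$cell_speed,
              if (x$direction < 0) "-x" else "+x"))
  cat(sprintf("  puncta birth front/back: %g / %g events/um^2/min\n",
              x$puncta_birth_rate_front, x$puncta_birth_rate_back))
  cat(sprintf("  growth front/back: %g / %g per min; death scale %g/min, stability threshold %g\n",
              x$puncta_growth_rate_front, x$puncta_growth_rate_back,
              x$death_rate_scale, x$mass_stability_threshold))
  invisible(x)
}
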
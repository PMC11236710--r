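#' Write a multichannel movie as a multi-page 16-bit TIFF
#'
#' Pages are ordered frame-major, channel-minor (`t1c1, t1c2, ...`). Pixel
#' size, frame interval, shape and channel names are stored in a JSON
#' sidecar (`<path>.json`), so [read_movie()] restores the full array and
#' its metadata. Movies rendered by [render_movie()] hold 16-bit integer
#' values and round-trip bit-exactly.
#'
#' @param movie array `(T, C, Y, X)` with `pixel_size` / `frame_interval`
#'   attributes (an `mcs_movie`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie)
  stopifnot(length(d) == 4)
  meta <- list(shape = d,
               channels = dimnames(movie)[[2]],
               pixel_size = attr(movie, "pixel_size"),
               frame_interval = attr(movie, "frame_interval"))
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      i <- i + 1L
      pages[[i]] <- matrix(movie[t, ch, , ], d[3], d[4]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a movie written by [write_movie()] (or any TIFF stack)
#'
#' Restores the `(T, C, Y, X)` array with metadata from the JSON sidecar
#' when present. Plain single- or multi-page TIFFs without a sidecar are
#' normalized to `T = pages, C = 1`; missing pixel size or interval can be
#' supplied and is otherwise filled with 1 and a warning.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval fallbacks when the file has no
#'   metadata.
#' @return An `mcs_movie` array.
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
  }
  if (!is.null(meta) && !is.null(meta$shape)) {
    d <- as.integer(meta$shape)
    if (length(pages) != d[1] * d[2]) {
      stop(sprintf("dimension mismatch: %d pages found, metadata promises T=%d C=%d",
                   length(pages), d[1], d[2]))
    }
  } else {
    d <- c(length(pages), 1L, nrow(pages[[1]]), ncol(pages[[1]]))
    meta <- list(channels = NULL)
  }
  movie <- array(0, dim = d, dimnames = list(NULL, meta$channels, NULL, NULL))
  i <- 0L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      i <- i + 1L
      pg <- pages[[i]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      movie[t, ch, , ] <- round(pg * 65535)
    }
  }
  ps <- meta$pixel_size %||% pixel_size
  fi <- meta$frame_interval %||% frame_interval
  if (is.null(ps)) { warning("no pixel size available; assuming 1 um/px"); ps <- 1 }
  if (is.null(fi)) { warning("no frame interval available; assuming 1 s"); fi <- 1 }
  attr(movie, "pixel_size") <- ps
  attr(movie, "frame_interval") <- fi
  class(movie) <- c("mcs_movie", class(movie))
  movie
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Bundles the scene configuration, the analysis-stage parameters and the
#' channel map into one validated object that [run_pipeline()] consumes.
#' Round-trips through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param scene a [scene_config()] (also the source of pixel size, frame
#'   interval and camera offset for the analysis stages).
#' @param channel_map named list mapping the roles `pm`, `er`, `mapper`
#'   (and optionally `nuclei`, `ptyr`) to channel names in the movie.
#' @param n_bins gradient bins (default 20).
#' @param normalize_profiles per-frame normalization by the whole-cell mean
#'   before cross-frame/cell averaging (default TRUE).
#' @param denom_floor ratio denominator floor in offset-subtracted
#'   intensity units.
#' @param tophat_radius_px,threshold_band,min_punctum_area puncta detection
#'   parameters (see [detect_puncta()]).
#' @param puncta_max_disp_px puncta linking gate (px).
#' @param cell_max_disp_um cell linking gate (um); default twice the
#'   configured cell displacement per frame.
#' @param mass_weight linking mass weight.
#' @param ring_width_um peripheral ring width (um).
#' @param seed pipeline seed (defaults to the scene seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene = scene_config(),
                            channel_map = list(pm = "CAAX", er = "SEC61B",
                                               mapper = "MAPPER"),
                            n_bins = 20L,
                            normalize_profiles = TRUE,
                            denom_floor = 50,
                            tophat_radius_px = 3L,
                            threshold_band = c(0.35, 0.45),
                            min_punctum_area = 2L,
                            puncta_max_disp_px = 3,
                            cell_max_disp_um = NULL,
                            mass_weight = 1,
                            ring_width_um = 3,
                            seed = NULL) {
  if (is.null(cell_max_disp_um)) {
    cell_max_disp_um <- max(2 * scene$cell_speed * scene$frame_interval / 60, 1)
  }
  cfg <- list(scene = scene, channel_map = channel_map,
              n_bins = as.integer(n_bins),
              normalize_profiles = isTRUE(normalize_profiles),
              denom_floor = denom_floor,
              tophat_radius_px = as.integer(tophat_radius_px),
              threshold_band = threshold_band,
              min_punctum_area = as.integer(min_punctum_area),
              puncta_max_disp_px = puncta_max_disp_px,
              cell_max_disp_um = cell_max_disp_um,
              mass_weight = mass_weight,
              ring_width_um = ring_width_um,
              seed = as.integer(seed %||% scene$seed))
  stopifnot("pm" %in% names(cfg$channel_map),
            cfg$n_bins >= 2L, cfg$denom_floor > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  scene <- do.call(scene_config, x$scene[setdiff(names(x$scene), character(0))])
  do.call(pipeline_config, c(list(scene = scene),
                             x[setdiff(names(x), "scene")]))
}

# stable hash of a pipeline configuration, recorded in every run report
config_hash <- function(config) rlang::hash(unclass(config))
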
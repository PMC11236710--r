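#' Simulate ground-truth contact-site puncta
#'
#' Puncta are born as a spatial Poisson process inside the instantaneous cell
#' footprint, with a birth-rate field linear in the normalized front-to-back
#' coordinate `p` (anchored at the half centres, see [scene_config()]). Each
#' punctum is stationary in the lab frame from birth; its mass grows at the
#' position-dependent rate and it dies with a hazard that decreases linearly
#' in its current mass, reaching zero at the stability threshold. A punctum
#' overtaken by the rear of the moving cell (its position leaves the mask) is
#' also terminated.
#'
#' @param config a [scene_config()].
#' @param geometry output of [simulate_cell_geometry()].
#' @return A `puncta_truth` list with `puncta` (one row per punctum:
#'   `id, birth_frame, death_frame, y, x, mass_birth, mass_final, exited`,
#'   with `death_frame = NA` for puncta alive at the last frame) and
#'   `observations` (one row per punctum per frame alive:
#'   `id, frame, y, x, mass, p`). Positions are lab-frame pixels and are
#'   constant within each track by construction.
#' @export
simulate_puncta <- function(config, geometry) {
  cfg <- validate_scene_config(config)
  set.seed(cfg$seed + 1L)
  dt_min <- cfg$frame_interval / 60
  px_area_um2 <- cfg$pixel_size^2

  # live-state vectors
  id <- integer(0); py <- numeric(0); px <- numeric(0)
  mass <- numeric(0); birth <- integer(0)
  next_id <- 1L
  rows_p <- list(); rows_o <- list()

  finish <- function(i, frame, exited) {
    rows_p[[length(rows_p) + 1L]] <<- data.frame(
      id = id[i], birth_frame = birth[i], death_frame = frame,
      y = py[i], x = px[i], mass_final = mass[i], exited = exited)
    keep <- setdiff(seq_along(id), i)
    id <<- id[keep]; py <<- py[keep]; px <<- px[keep]
    mass <<- mass[keep]; birth <<- birth[keep]
  }

  mass_birth <- numeric(0)  # lookup by id
  for (t in seq_len(cfg$n_frames)) {
    ## births at frame t
    m <- geometry$masks[[t]]
    idx <- which(m, arr.ind = TRUE)
    p_pix <- true_axial_position(geometry, idx[, 2], t)
    lam <- birth_rate_at(cfg, p_pix)              # events/um^2/min
    mu <- lam * px_area_um2 * dt_min              # expected births per pixel
    nb <- stats::rpois(length(mu), mu)
    born <- which(nb > 0)
    if (length(born) > 0) {
      reps <- rep(born, nb[born])
      n_new <- length(reps)
      new_y <- idx[reps, 1] + stats::runif(n_new, -0.5, 0.5)
      new_x <- idx[reps, 2] + stats::runif(n_new, -0.5, 0.5)
      new_m <- cfg$initial_mass *
        exp(stats::rnorm(n_new, 0, cfg$initial_mass_sdlog))
      new_ids <- seq.int(next_id, length.out = n_new)
      next_id <- next_id + n_new
      id <- c(id, new_ids); py <- c(py, new_y); px <- c(px, new_x)
      mass <- c(mass, new_m); birth <- c(birth, rep(t, n_new))
      mass_birth[new_ids] <- new_m
    }

    ## record observations of every live punctum at frame t
    if (length(id) > 0) {
      p_now <- true_axial_position(geometry, px, t)
      rows_o[[length(rows_o) + 1L]] <- data.frame(
        id = id, frame = t, y = py, x = px, mass = mass, p = p_now)
    }

    if (t == cfg$n_frames) break

    ## transition t -> t+1: growth, death, exit
    if (length(id) > 0) {
      p_now <- true_axial_position(geometry, px, t)
      g <- ifelse(p_now < 0.5, cfg$puncta_growth_rate_front,
                  cfg$puncta_growth_rate_back)
      mass <- mass + g * dt_min
      haz <- cfg$death_rate_scale *
        pmax(0, 1 - mass / cfg$mass_stability_threshold)
      dies <- stats::runif(length(id)) < (1 - exp(-haz * dt_min))
      m_next <- geometry$masks[[t + 1L]]
      iy <- pmin(pmax(round(py), 1L), nrow(m_next))
      ix <- pmin(pmax(round(px), 1L), ncol(m_next))
      outside <- !m_next[cbind(iy, ix)]
      gone <- which(dies | outside)
      if (length(gone) > 0) finish(gone, t, exited = outside[gone] & !dies[gone])
    }
  }

  ## survivors are censored by the movie end
  if (length(id) > 0) {
    rows_p[[length(rows_p) + 1L]] <- data.frame(
      id = id, birth_frame = birth, death_frame = NA_integer_,
      y = py, x = px, mass_final = mass, exited = FALSE)
  }

  puncta <- if (length(rows_p) > 0) do.call(rbind, rows_p) else
    data.frame(id = integer(0), birth_frame = integer(0),
               death_frame = integer(0), y = numeric(0), x = numeric(0),
               mass_final = numeric(0), exited = logical(0))
  obs <- if (length(rows_o) > 0) do.call(rbind, rows_o) else
    data.frame(id = integer(0), frame = integer(0), y = numeric(0),
               x = numeric(0), mass = numeric(0), p = numeric(0))
  puncta <- puncta[order(puncta$id), , drop = FALSE]
  puncta$mass_birth <- unname(mass_birth[puncta$id])
  obs <- obs[order(obs$id, obs$frame), , drop = FALSE]
  rownames(puncta) <- rownames(obs) <- NULL

  structure(list(puncta = puncta, observations = obs, config = cfg),
            class = "puncta_truth")
}

# birth-rate field: linear in p, anchored at the half centres p = 0.25/0.75,
# clamped at zero
birth_rate_at <- function(cfg, p) {
  lf <- cfg$puncta_birth_rate_front
  lb <- cfg$puncta_birth_rate_back
  pmax(0, lf + (lb - lf) * (p - 0.25) / 0.5)
}

#' Monte Carlo sampler of the punctum birth-death mass model
#'
#' Runs the same discrete-time growth/death model used by
#' [simulate_puncta()] for a cohort of puncta at a fixed axial position,
#' without any imaging. Useful for calibrating and testing the
#' lifetime-versus-mass relationship at large n.
#'
#' @param n number of puncta.
#' @param mass0 initial masses (recycled to length `n`).
#' @param growth_rate mass growth per minute.
#' @param death_rate_scale,mass_stability_threshold hazard parameters as in
#'   [scene_config()].
#' @param dt_min frame interval in minutes.
#' @param max_frames censoring horizon in frames.
#' @return Data frame `id, mass_birth, mass_final, lifetime_frames,
#'   lifetime_s, censored`. Lifetime counts frames from appearance to
#'   disappearance (or the last frame) inclusive, times the interval.
#' @export
simulate_lifetimes <- function(n, mass0 = 1, growth_rate = 0,
                               death_rate_scale = 0.5,
                               mass_stability_threshold = Inf,
                               dt_min = 1 / 3, max_frames = 1000L) {
  m <- rep_len(mass0, n)
  m0 <- m
  alive <- rep(TRUE, n)
  life <- rep(1L, n)
  for (t in seq_len(max_frames - 1L)) {
    if (!any(alive)) break
    m[alive] <- m[alive] + growth_rate * dt_min
    haz <- death_rate_scale * pmax(0, 1 - m[alive] / mass_stability_threshold)
    dies <- stats::runif(sum(alive)) < (1 - exp(-haz * dt_min))
    idx <- which(alive)
    life[idx[!dies]] <- life[idx[!dies]] + 1L
    alive[idx[dies]] <- FALSE
  }
  data.frame(id = seq_len(n), mass_birth = m0, mass_final = m,
             lifetime_frames = life, lifetime_s = life * dt_min * 60,
             censored = alive)
}
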
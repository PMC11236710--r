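test_that("cell geometry advances at the configured speed and is reproducible", {
  # 1 um/min at 120 s intervals = 2 um per frame
  cfg <- tiny_scene_config(cell_speed = 1, frame_interval = 120, seed = 1)
  geom <- simulate_cell_geometry(cfg)
  dx <- diff(geom$centroids$x) * cfg$pixel_size
  expect_equal(dx, rep(-2, cfg$n_frames - 1), tolerance = 1e-6)
  dy <- diff(geom$centroids$y)
  expect_equal(dy, rep(0, cfg$n_frames - 1))

  still <- simulate_cell_geometry(tiny_scene_config(cell_speed = 0))
  for (t in 2:length(still$masks)) {
    expect_identical(still$masks[[t]], still$masks[[1]])
  }

  g1 <- simulate_cell_geometry(tiny_scene_config(seed = 0))
  g2 <- simulate_cell_geometry(tiny_scene_config(seed = 0))
  expect_identical(g1$masks, g2$masks)

  expect_error(
    simulate_cell_geometry(tiny_scene_config(cell_speed = 20, n_frames = 30L)),
    "field of view")
})

test_that("cell mask is a single component with the tip farthest from the centroid", {
  geom <- simulate_cell_geometry(tiny_scene_config(seed = 2))
  m <- geom$masks[[1]]
  expect_equal(max(EBImage::bwlabel(m * 1)), 1)
  idx <- which(m, arr.ind = TRUE)
  ctr <- colMeans(idx)
  b <- which(m & !EBImage::erode(m * 1, EBImage::makeBrush(3, "disc")) > 0,
             arr.ind = TRUE)
  d <- sqrt((b[, 1] - ctr[1])^2 + (b[, 2] - ctr[2])^2)
  tip <- b[which.max(d), ]
  # migration towards -x: the tip is the leftmost extreme
  expect_equal(unname(tip[2]), min(idx[, 2]))
})

test_that("puncta are stationary in the lab frame and every rendered punctum is tabulated", {
  cfg <- tiny_scene_config(seed = 3)
  geom <- simulate_cell_geometry(cfg)
  truth <- simulate_puncta(cfg, geom)
  o <- truth$observations
  pos_spread <- tapply(o$x, o$id, function(x) diff(range(x))) +
    tapply(o$y, o$id, function(y) diff(range(y)))
  expect_true(all(pos_spread == 0))
  expect_setequal(unique(o$id), truth$puncta$id)
  # censoring bookkeeping: death_frame NA iff alive at the last frame
  last <- tapply(o$frame, o$id, max)
  alive_end <- names(last)[last == cfg$n_frames]
  p <- truth$puncta
  died <- p$id[!is.na(p$death_frame)]
  expect_true(all(p$death_frame[!is.na(p$death_frame)] < cfg$n_frames) ||
                all(tapply(o$frame, o$id, max)[as.character(died)] ==
                      p$death_frame[!is.na(p$death_frame)]))
})

test_that("equal front/back birth rates give spatially uniform occupancy", {
  # chi-square of front- vs back-half counts against the area split
  cfg <- scene_config(cell_speed = 0, n_frames = 10L,
                      puncta_birth_rate_front = 0.05,
                      puncta_birth_rate_back = 0.05,
                      puncta_growth_rate_front = 0, puncta_growth_rate_back = 0,
                      death_rate_scale = 0.3, mass_stability_threshold = Inf,
                      seed = 4)
  geom <- simulate_cell_geometry(cfg)
  truth <- simulate_puncta(cfg, geom)
  o <- truth$observations
  m <- geom$masks[[1]]
  p_pix <- true_axial_position(geom, which(m, arr.ind = TRUE)[, 2], 1)
  area_split <- c(mean(p_pix < 0.5), mean(p_pix >= 0.5))
  counts <- c(sum(o$p < 0.5), sum(o$p >= 0.5))
  pv <- stats::chisq.test(counts, p = area_split)$p.value
  expect_gt(pv, 0.01)
})

test_that("constant hazard of 0.5/min gives ~2 min mean lifetimes (exponential oracle)", {
  dt_min <- 1 / 3
  n <- 1e4
  lt <- simulate_lifetimes(n, mass0 = 1, growth_rate = 0,
                           death_rate_scale = 0.5,
                           mass_stability_threshold = Inf,
                           dt_min = dt_min, max_frames = 2000L)
  expect_true(all(!lt$censored))
  # independent oracle: continuous exponential lifetimes discretized with
  # the same appearance-to-disappearance frame counting
  set.seed(99)
  oracle_frames <- floor(stats::rexp(n, rate = 0.5) / dt_min) + 1
  oracle_mean <- mean(oracle_frames) * dt_min
  se <- sqrt(stats::var(lt$lifetime_frames * dt_min) / n +
               stats::var(oracle_frames * dt_min) / n)
  impl_mean <- mean(lt$lifetime_s) / 60
  expect_lt(abs(impl_mean - oracle_mean), 3 * se)
  # both converge to the continuous 1/hazard = 2 min as dt -> 0
  lt2 <- simulate_lifetimes(n, growth_rate = 0, death_rate_scale = 0.5,
                            mass_stability_threshold = Inf, dt_min = 1 / 60,
                            max_frames = 5000L)
  expect_lt(abs(mean(lt2$lifetime_s) / 60 - 2), 0.1)
})

test_that("3x back growth rate triples back-half mass increments", {
  incs_f <- incs_b <- numeric(0)
  for (s in 1:7) {
    cfg <- scene_config(seed = 100 + s, puncta_birth_rate_front = 0.04,
                        puncta_birth_rate_back = 0.04,
                        puncta_growth_rate_front = 0.2,
                        puncta_growth_rate_back = 0.6,
                        death_rate_scale = 0.2,
                        mass_stability_threshold = Inf)
    geom <- simulate_cell_geometry(cfg)
    o <- simulate_puncta(cfg, geom)$observations
    o <- o[order(o$id, o$frame), ]
    same <- o$id[-1] == o$id[-nrow(o)]
    i <- which(same)
    dm <- o$mass[i + 1] - o$mass[i]
    at_back <- o$p[i] >= 0.5
    incs_f <- c(incs_f, dm[!at_back])
    incs_b <- c(incs_b, dm[at_back])
  }
  expect_gt(length(incs_f) + length(incs_b), 5e3)
  expect_equal(mean(incs_b) / mean(incs_f), 3, tolerance = 0.1)
})

test_that("rendering integrates Gaussian spots to their analytic mass", {
  img <- matrix(0, 64, 64)
  img <- add_gaussian_spots(img, 30.37, 33.81, sigma_px = 1.1,
                            amplitude = 5000)
  # closed form: the pixel-box integrals sum to the full Gaussian integral
  # up to window truncation
  expect_equal(sum(img), 5000, tolerance = 0.02 * 5000)
  expect_equal(sum(img * col(img)) / sum(img), 33.81, tolerance = 1e-3)

  # zero noise, no puncta: reporter channel is identically the offset
  cfg <- tiny_scene_config(puncta_birth_rate_front = 0,
                           puncta_birth_rate_back = 0,
                           noise_gaussian_sd = 0, noise_poisson_gain = 0)
  sc <- simulate_scene(cfg)
  expect_true(all(sc$movie[, "MAPPER", , ] == cfg$camera_offset))
})

test_that("the whole scene is bit-reproducible under a fixed seed", {
  cfg <- tiny_scene_config(seed = 7)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$movie, s2$movie)
  expect_identical(s1$truth$puncta, s2$truth$puncta)
  expect_identical(s1$truth$observations, s2$truth$observations)
})

test_that("back:front count ratio converges to the configured density ratio", {
  # stationary scenes so the steady-state density ratio equals the
  # configured half-anchored birth ratio. Density is measured per axial bin
  # (count over bin area) and the halves averaged with equal bin weights,
  # matching how the gradient profiles average their 20 segments; the cell
  # outline tapers, so area-weighted half counts would mix the linear birth
  # field differently.
  n_bins <- 20L
  counts <- areas <- numeric(n_bins)
  for (s in 1:25) {
    cfg <- scene_config(cell_speed = 0, n_frames = 8L,
                        puncta_birth_rate_front = 0.02,
                        puncta_birth_rate_back = 0.04,
                        puncta_growth_rate_front = 0,
                        puncta_growth_rate_back = 0,
                        death_rate_scale = 0.3,
                        mass_stability_threshold = Inf, seed = 200 + s)
    geom <- simulate_cell_geometry(cfg)
    o <- simulate_puncta(cfg, geom)$observations
    m <- geom$masks[[1]]
    p_pix <- true_axial_position(geom, which(m, arr.ind = TRUE)[, 2], 1)
    bin_o <- pmin(floor(o$p * n_bins), n_bins - 1L) + 1L
    bin_a <- pmin(floor(p_pix * n_bins), n_bins - 1L) + 1L
    counts <- counts + tabulate(bin_o, n_bins)
    areas <- areas + tabulate(bin_a, n_bins) * cfg$n_frames
  }
  dens <- counts / areas
  dens_ratio <- mean(dens[11:20]) / mean(dens[1:10])
  expect_equal(dens_ratio, 2, tolerance = 0.1)
})
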
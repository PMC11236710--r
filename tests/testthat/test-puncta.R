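test_that("spot detection recovers positions and masses at zero noise", {
  set.seed(21)
  ny <- 60; nx <- 200
  n <- 10
  ys <- runif(n, 15, 45); xs <- seq(20, 180, length.out = n) + runif(n, -2, 2)
  mass_true <- runif(n, 4000, 6000)
  img <- add_gaussian_spots(matrix(0, ny, nx), ys, xs, 0.8, mass_true)
  img <- round(img + 100)
  mask <- matrix(TRUE, ny, nx)
  det <- detect_puncta(img, mask, full_frame_axis(ny, nx))
  expect_equal(nrow(det), n)
  m <- match_to_truth(det, data.frame(y = ys, x = xs))
  expect_true(all(m$dist < 0.5))
  expect_true(all(abs(det$mass / mass_true[m$idx] - 1) < 0.05))
  # mass identity and axial coordinate bounds
  expect_equal(det$mass, det$mean_intensity * det$area, tolerance = 1e-9)
  expect_true(all(det$p >= 0 & det$p <= 1))
  # total detected mass conserves total rendered mass within 5%
  expect_equal(sum(det$mass), sum(mass_true), tolerance = 0.05)

  flat <- matrix(137, ny, nx)
  expect_equal(nrow(detect_puncta(flat, mask, full_frame_axis(ny, nx))), 0)
})

test_that("thresholding at the 40% band keeps dim front spots detectable", {
  # graded cell: dim spots in the front half, bright spots in the back half
  set.seed(22)
  ny <- 60; nx <- 200
  front_x <- seq(15, 90, by = 11); back_x <- seq(110, 190, by = 11)
  img <- add_gaussian_spots(matrix(0, ny, nx),
                            rep(30, length(front_x)), front_x, 0.8, 1200)
  img <- add_gaussian_spots(img, rep(30, length(back_x)), back_x, 0.8, 12000)
  img <- round(img + 100)
  mask <- matrix(TRUE, ny, nx)
  ax <- full_frame_axis(ny, nx)
  band <- detect_puncta(img, mask, ax, threshold_band = c(0.35, 0.45))
  from_back <- detect_puncta(img, mask, ax, threshold_band = c(0.75, 0.95))
  n_front_band <- sum(band$p < 0.5)
  n_front_back <- sum(from_back$p < 0.5)
  expect_gt(n_front_band, n_front_back)
  expect_equal(n_front_band, length(front_x))

  # empty band falls back to the whole mask with a warning
  ax_hi <- full_frame_axis(ny, nx)
  ax_hi$p <- matrix(0.9, ny, nx)
  mask_part <- matrix(FALSE, ny, nx); mask_part[, 100:200] <- TRUE
  expect_warning(detect_puncta(img, mask_part, ax_hi), "threshold band")
})

test_that("lifetimes and censoring follow the appearance-to-disappearance rule", {
  obs <- data.frame(frame = 3:7, y = 10, x = 10, mass = 100)
  lk <- link_puncta(obs, n_frames = 20, frame_interval = 20)
  expect_equal(lk$tracks$lifetime_s, 5 * 20)
  expect_false(lk$tracks$censored)

  obs2 <- data.frame(frame = 16:20, y = 10, x = 10, mass = 100)
  lk2 <- link_puncta(obs2, n_frames = 20, frame_interval = 20)
  expect_true(lk2$tracks$censored)
  expect_equal(lk2$tracks$lifetime_s, 5 * 20)
})

test_that("ground-truth puncta tracks are recovered whole at low density", {
  recs <- vapply(1:4, function(s) {
    cfg <- scene_config(seed = 300 + s, frame_interval = 20, n_frames = 15L,
                        puncta_birth_rate_front = 0.01,
                        puncta_birth_rate_back = 0.03,
                        puncta_growth_rate_front = 0,
                        puncta_growth_rate_back = 0,
                        death_rate_scale = 0.3,
                        mass_stability_threshold = Inf)
    geom <- simulate_cell_geometry(cfg)
    truth <- simulate_puncta(cfg, geom)
    # confirm the density regime of the fidelity claim
    dens <- max(table(truth$observations$frame)) / sum(geom$masks[[1]])
    expect_lte(dens, 0.02)
    track_recovery_fraction(truth)
  }, numeric(1))
  expect_gte(mean(recs), 0.95)
})

test_that("lifetime-mass profiles are monotone only under mass-dependent hazard", {
  set.seed(23)
  mass0 <- exp(rnorm(1000, 0, 0.6))
  dep <- simulate_lifetimes(1000, mass0 = mass0, growth_rate = 0,
                            death_rate_scale = 1.2,
                            mass_stability_threshold = 3,
                            dt_min = 1 / 3, max_frames = 400L)
  binned <- lifetime_vs_mass(dep, breaks = 8, mass_col = "mass_birth")
  unc <- !dep$censored
  ct <- stats::cor.test(dep$mass_birth[unc], dep$lifetime_s[unc],
                        method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  ok <- !is.na(binned$mean_lifetime_s)
  expect_gt(stats::cor(binned$mass_mid[ok], binned$mean_lifetime_s[ok],
                       method = "spearman"), 0)

  # constant hazard: flat profile, slope CI contains 0
  flat <- simulate_lifetimes(1000, mass0 = mass0, growth_rate = 0,
                             death_rate_scale = 0.5,
                             mass_stability_threshold = Inf,
                             dt_min = 1 / 3, max_frames = 2000L)
  bf <- lifetime_vs_mass(flat, breaks = 8, mass_col = "mass_birth")
  fit <- stats::lm(mean_lifetime_s ~ mass_mid, data = bf, weights = bf$n)
  ci <- stats::confint(fit, "mass_mid", level = 0.99)
  expect_true(ci[1] < 0 && ci[2] > 0)

  # fully censored input: no naive estimate, everything counted censored
  allc <- flat
  allc$censored <- TRUE
  bc <- lifetime_vs_mass(allc, breaks = 4, mass_col = "mass_birth")
  expect_true(all(is.na(bc$mean_lifetime_s)))
  expect_equal(sum(bc$n_censored), nrow(allc))
})

test_that("flow vectors decompose exactly and respect frame covariance", {
  obs <- data.frame(track_id = rep(1:3, each = 5), frame = rep(1:5, 3),
                    y = rep(c(10, 20, 30), each = 5) + rep(0:4, 3) * 0.1,
                    x = rep(c(15, 25, 35), each = 5) - rep(0:4, 3) * 0.2)
  cc <- data.frame(frame = 1:5, y = 25 + 0:4, x = 60 - 5 * (0:4))
  ff <- flow_field(obs, cc, pixel_size = 0.4, frame_interval = 120)
  v <- ff$vectors
  # cell-frame + cell displacement = lab-frame, per vector, exactly
  dyc <- diff(cc$y)[v$frame0]; dxc <- diff(cc$x)[v$frame0]
  expect_equal(v$dy_cell + dyc, v$dy_lab, tolerance = 1e-12)
  expect_equal(v$dx_cell + dxc, v$dx_lab, tolerance = 1e-12)

  # stationary cell: both frames identical
  cc0 <- data.frame(frame = 1:5, y = 25, x = 60)
  f0 <- flow_field(obs, cc0, 0.4, 120)
  expect_equal(f0$vectors$dy_cell, f0$vectors$dy_lab)
  expect_equal(f0$vectors$dx_cell, f0$vectors$dx_lab)

  # per-frame stage drift: lab vectors shift by the drift, cell-frame
  # vectors invariant
  drift <- 1.7
  obs_d <- obs; obs_d$x <- obs_d$x + drift * obs_d$frame
  cc_d <- cc; cc_d$x <- cc_d$x + drift * cc_d$frame
  fd <- flow_field(obs_d, cc_d, 0.4, 120)
  expect_equal(fd$vectors$dx_lab, v$dx_lab + drift, tolerance = 1e-12)
  expect_equal(fd$vectors$dx_cell, v$dx_cell, tolerance = 1e-12)
})

test_that("retrograde flow: stationary puncta move at cell speed in the cell frame", {
  cfg <- scene_config(seed = 33, puncta_birth_rate_front = 0.002,
                      puncta_birth_rate_back = 0.006,
                      puncta_growth_rate_front = 0, puncta_growth_rate_back = 0,
                      death_rate_scale = 0.2, mass_stability_threshold = Inf,
                      initial_mass = 2)
  sc <- simulate_scene(cfg)
  pa <- movie_puncta_analysis(sc$movie, pipeline_config(scene = cfg))
  s <- pa$flow$summary
  expect_lt(s$mean_lab_speed_um_min, 0.05 * cfg$cell_speed)
  expect_equal(s$mean_cell_frame_speed_um_min, cfg$cell_speed, tolerance = 0.1)
})
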
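test_that("the front is the tip farthest from the centroid, with stable tie-breaks", {
  geom <- simulate_cell_geometry(tiny_scene_config(seed = 51))
  m <- geom$masks[[1]]
  ax <- find_front(m)
  expect_false(ax$ambiguous)
  # migration towards -x: the detected tip is at the leftmost mask column
  expect_equal(unname(ax$front[2]), min(which(m, arr.ind = TRUE)[, 2]),
               tolerance = 1)
  # p increases front to back along the axis
  idx <- which(m, arr.ind = TRUE)
  expect_gt(stats::cor(ax$p[idx], idx[, 2]), 0.99)

  # mirrored mask gives the mirrored front
  mm <- m[, rev(seq_len(ncol(m)))]
  axm <- find_front(mm)
  expect_equal(unname(axm$front[2]), ncol(m) + 1 - unname(ax$front[2]))
  expect_equal(unname(axm$front[1]), unname(ax$front[1]))

  # a disk is ambiguous; a previous axis steers the choice continuously
  dm <- disk_mask(15)
  axd <- find_front(dm)
  expect_true(axd$ambiguous)
  axd2 <- find_front(dm, previous_axis = c(0, 1))
  expect_equal(unname(axd2$axis), c(0, 1), tolerance = 0.05)
})

test_that("ratio images honour identities and the denominator floor", {
  a <- matrix(runif(400, 1, 5), 20, 20)
  expect_true(all(ratio_image(a, a) == 1))
  expect_true(all(ratio_image(2 * a, a) == 2))
  low <- matrix(0.5, 20, 20)
  expect_error(ratio_image(a, low, floor = 1), "floor")
  part <- a; part[1:5, ] <- 0
  r <- ratio_image(a, part, floor = 0.5)
  expect_true(all(is.na(r[1:5, ])))
  expect_true(all(!is.na(r[6:20, ])))
})

test_that("binning partitions the mask and reproduces a linear field", {
  geom <- simulate_cell_geometry(tiny_scene_config(seed = 52))
  m <- geom$masks[[1]]
  ax <- find_front(m)

  vals <- matrix(2.5, nrow(m), ncol(m))
  pr <- bin_profile(vals, m, ax)
  expect_equal(sum(pr$n_pixels), sum(m))
  expect_equal(pr$mean, rep(2.5, 20))
  prn <- bin_profile(vals, m, ax, normalize = TRUE)
  expect_equal(prn$mean, rep(1, 20))

  # field equal to p: bin means near the bin centres
  pfield <- ax$p
  pfield[is.na(pfield)] <- 0
  pl <- bin_profile(pfield, m, ax)
  expect_equal(pl$mean, (seq_len(20) - 0.5) / 20, tolerance = 0.03)

  # conservation: sum over bins of mean x valid count = sum of valid pixels
  set.seed(1)
  noisy <- matrix(runif(length(m)), nrow(m))
  noisy[sample(which(m), 50)] <- NA
  pn <- bin_profile(noisy, m, ax)
  expect_equal(sum(pn$mean * pn$n_valid),
               sum(noisy[m], na.rm = TRUE), tolerance = 1e-9)

  # reversed axis reverses the profile exactly (sub-pixel axis endpoints so
  # no pixel projects exactly onto a bin edge)
  ax_o <- ax
  ax_o$front <- ax$front + c(0.013, -0.271)
  ax_o$back <- ax$back + c(-0.017, 0.309)
  ax_o$length_px <- sqrt(sum((ax_o$back - ax_o$front)^2))
  ax_o$axis <- (ax_o$back - ax_o$front) / ax_o$length_px
  ax_rev <- ax_o
  ax_rev$front <- ax_o$back; ax_rev$back <- ax_o$front
  ax_rev$axis <- -ax_o$axis
  pv <- bin_profile(noisy, m, ax_o)
  pvr <- bin_profile(noisy, m, ax_rev)
  expect_equal(pvr$mean, rev(pv$mean), tolerance = 1e-9)
  expect_equal(pvr$n_pixels, rev(pv$n_pixels))
})

test_that("kymographs stack profiles and average with zero spread when static", {
  p1 <- 1:20
  k <- assemble_kymograph(list(p1, p1, p1))
  expect_equal(dim(k$matrix), c(20L, 3L))
  expect_true(all(k$sd == 0))
  expect_equal(k$mean, as.numeric(p1))

  flipped <- assemble_kymograph(list(p1, p1, rev(p1), rev(p1)))
  expect_equal(flipped$matrix[, 3], rev(flipped$matrix[, 1]))

  holey <- assemble_kymograph(list(p1, NULL, p1))
  expect_equal(holey$missing_frames, 2L)
  expect_true(all(is.na(holey$matrix[, 2])))
  expect_equal(holey$mean, as.numeric(p1))

  expect_error(assemble_kymograph(list(1:20, 1:10)), "equal length")
})

test_that("steepness scores match the direct-arithmetic oracle", {
  u <- steepness(rep(3.7, 20))
  expect_equal(u$score20, 0)
  expect_equal(u$ratio50, 1)
  expect_equal(u$log2_ratio50, 0)

  s <- steepness(1:20)
  # oracle computed directly from the definitions
  expect_equal(s$score20, abs(mean(1:4) - mean(17:20)) / mean(17:20),
               tolerance = 1e-12)
  expect_equal(s$score20, 16 / 18.5, tolerance = 1e-12)
  expect_equal(s$ratio50, 5.5 / 15.5, tolerance = 1e-12)

  # scale invariance
  s2 <- steepness(7.3 * (1:20))
  expect_equal(s2$score20, s$score20, tolerance = 1e-12)
  expect_equal(s2$ratio50, s$ratio50, tolerance = 1e-12)

  expect_error(steepness(c(rep(1, 16), rep(0, 4))), "zero back")
})

test_that("front/back summaries follow the fraction and match the halves at 0.5", {
  expect_equal(front_back_summary(rep(2, 20)),
               list(front = 2, back = 2))
  fb <- front_back_summary(1:20, fraction = 0.2)
  expect_equal(fb$front, 2.5)
  expect_equal(fb$back, 18.5)
  h <- front_back_summary(1:20, fraction = 0.5)
  s <- steepness(1:20)
  expect_equal(h$front / h$back, s$ratio50, tolerance = 1e-12)
  expect_error(front_back_summary(1:20, fraction = 0.7), "fraction")
  expect_error(front_back_summary(1:20, fraction = 0), "fraction")
})

test_that("growth-rate slopes recover a uniform and a 3x back growth field", {
  mk_truth <- function(gf, gb, seeds) {
    out <- NULL
    for (s in seeds) {
      cfg <- scene_config(seed = s, image_shape = c(64L, 280L), n_frames = 24L,
                          puncta_birth_rate_front = 0.012,
                          puncta_birth_rate_back = 0,
                          puncta_growth_rate_front = gf,
                          puncta_growth_rate_back = gb,
                          death_rate_scale = 0, initial_mass_sdlog = 0.25)
      geom <- simulate_cell_geometry(cfg)
      o <- simulate_puncta(cfg, geom)$observations
      out <- rbind(out, data.frame(track_id = o$id + s * 1e7, p = o$p,
                                   ratio = o$mass))
    }
    out
  }
  eq <- growth_rate_curve(mk_truth(0.4, 0.4, 401:403))
  expect_equal(eq$slope_ratio, 1, tolerance = 0.15)
  tri <- growth_rate_curve(mk_truth(0.2, 0.6, 404:406))
  expect_equal(tri$slope_ratio, 3, tolerance = 0.15)

  # a stationary cell never builds up a p range: degenerate input signals
  cfg0 <- scene_config(seed = 407, cell_speed = 0,
                       puncta_birth_rate_front = 0.02,
                       puncta_birth_rate_back = 0,
                       death_rate_scale = 0)
  geom0 <- simulate_cell_geometry(cfg0)
  o0 <- simulate_puncta(cfg0, geom0)$observations
  expect_error(growth_rate_curve(
    data.frame(track_id = o0$id, p = o0$p, ratio = o0$mass),
    complete_min_p = 0), "insufficient p range")
})

test_that("profiles and steepness are invariant to global intensity scaling", {
  cfg <- tiny_scene_config(seed = 53, noise_gaussian_sd = 0,
                           noise_poisson_gain = 0, camera_offset = 0)
  sc <- simulate_scene(cfg)
  pc <- pipeline_config(scene = cfg)
  g1 <- movie_gradient_analysis(sc$movie, pc)
  scaled <- sc$movie
  scaled[] <- scaled[] * 3
  g2 <- movie_gradient_analysis(scaled, pc)
  expect_equal(g2$steepness$score20, g1$steepness$score20, tolerance = 1e-6)
  expect_equal(g2$steepness$ratio50, g1$steepness$ratio50, tolerance = 1e-6)
})
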
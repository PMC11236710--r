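# shared fixture builders; everything is generated in code at test time

# small, fast default scene
tiny_scene_config <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(56L, 160L), n_frames = 8L, cell_length = 30),
    list(...))
  do.call(scene_config, args)
}

# disk mask of the given radius on an odd-sized square frame
disk_mask <- function(radius, half = radius + 30L) {
  n <- 2L * half + 1L
  ctr <- half + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= radius^2)
}

# axis frame spanning a full-frame mask left to right (for isolated
# detect_puncta tests); front just outside the first column so p never sits
# exactly on a bin edge
full_frame_axis <- function(ny, nx) {
  p <- matrix(rep((seq_len(nx) - 0.4) / (nx + 0.2), each = ny), ny, nx)
  structure(list(front = c((ny + 1) / 2, 0.4),
                 back = c((ny + 1) / 2, nx + 0.6),
                 axis = c(0, 1), length_px = nx + 0.2,
                 p = pmin(pmax(p, 0), 1), ambiguous = FALSE),
            class = "axis_frame")
}

# match detections to ground-truth observations of one frame by nearest
# neighbour; returns per-detection distance and the matched truth row
match_to_truth <- function(det, truth) {
  d <- sqrt(outer(det$y, truth$y, "-")^2 + outer(det$x, truth$x, "-")^2)
  list(dist = apply(d, 1, min), idx = apply(d, 1, which.min))
}

# fraction of ground-truth puncta tracks recovered whole (one recovered
# track holding exactly that punctum's observations) after linking the
# ground-truth observation table
track_recovery_fraction <- function(truth, max_disp = 3, mass_scale = 2000) {
  o <- truth$observations
  obs <- data.frame(frame = o$frame, y = o$y, x = o$x,
                    mass = o$mass * mass_scale)
  linked <- link_observations(obs, max_disp = max_disp, mass_weight = 1)
  key <- paste(linked$frame, round(linked$y, 6), round(linked$x, 6))
  gtkey <- paste(o$frame, round(o$y, 6), round(o$x, 6))
  linked$gt_id <- o$id[match(key, gtkey)]
  tab <- table(linked$gt_id, linked$track_id)
  ok <- 0L
  for (g in rownames(tab)) {
    tid <- colnames(tab)[tab[g, ] > 0]
    if (length(tid) == 1 && sum(tab[, tid] > 0) == 1) ok <- ok + 1L
  }
  ok / nrow(truth$puncta)
}
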
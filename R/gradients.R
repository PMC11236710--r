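#' Identify the cell front and the front-to-back axis
#'
#' The front is the boundary point with the farthest distance from the mask
#' centroid (the tip end); the back is the boundary point farthest from the
#' front. Every mask pixel gets a normalized axial coordinate `p` in
#' `[0, 1]` (0 at the front) by scalar projection onto the front-to-back
#' axis, clipped to the unit interval. For nearly circular masks the tip is
#' ambiguous; the result is flagged and the tie is broken towards the
#' smaller x (then smaller y), or, when `previous_axis` is supplied, towards
#' the candidate most aligned with it.
#'
#' @param mask logical cell mask (one connected component).
#' @param previous_axis optional length-2 axis vector `(y, x)` from the
#'   previous frame, used to stabilize the tip choice over time.
#' @return An `axis_frame` list: `front` and `back` `(y, x)` points, unit
#'   `axis` vector front to back, `length_px`, `p` (matrix, `NA` outside
#'   the mask) and `ambiguous` flag.
#' @export
find_front <- function(mask, previous_axis = NULL) {
  stopifnot(is.matrix(mask), any(mask))
  boundary <- mask & !ebi_erode(mask, 1L)
  bidx <- which(boundary, arr.ind = TRUE)
  if (nrow(bidx) == 0) bidx <- which(mask, arr.ind = TRUE)
  cidx <- which(mask, arr.ind = TRUE)
  ctr <- c(mean(cidx[, 1]), mean(cidx[, 2]))
  d <- sqrt((bidx[, 1] - ctr[1])^2 + (bidx[, 2] - ctr[2])^2)
  dmax <- max(d)
  ambiguous <- (dmax - stats::median(d)) / dmax < 0.05

  cand <- which(d >= dmax - 0.5)
  # the axis points front -> back, so the front lies against it
  front <- pick_candidate(bidx[cand, , drop = FALSE], ctr,
                          if (!is.null(previous_axis)) -previous_axis)

  d2 <- sqrt((bidx[, 1] - front[1])^2 + (bidx[, 2] - front[2])^2)
  cand2 <- which(d2 >= max(d2) - 0.5)
  back <- pick_candidate(bidx[cand2, , drop = FALSE], front,
                         if (!is.null(previous_axis)) previous_axis else NULL)

  len <- sqrt(sum((back - front)^2))
  axis <- (back - front) / len
  p <- matrix(NA_real_, nrow(mask), ncol(mask))
  proj <- ((cidx[, 1] - front[1]) * axis[1] +
             (cidx[, 2] - front[2]) * axis[2]) / len
  p[cidx] <- pmin(pmax(proj, 0), 1)

  structure(list(front = unname(front), back = unname(back),
                 axis = unname(axis), length_px = len, p = p,
                 ambiguous = ambiguous),
            class = "axis_frame")
}

# deterministic tie-break among candidate extremal boundary points
pick_candidate <- function(pts, origin, previous_axis = NULL) {
  if (nrow(pts) == 1) return(c(pts[1, 1], pts[1, 2]))
  if (!is.null(previous_axis)) {
    score <- (pts[, 1] - origin[1]) * previous_axis[1] +
      (pts[, 2] - origin[2]) * previous_axis[2]
    pts <- pts[order(-score, pts[, 2], pts[, 1]), , drop = FALSE]
  } else {
    pts <- pts[order(pts[, 2], pts[, 1]), , drop = FALSE]
  }
  c(pts[1, 1], pts[1, 2])
}

#' Per-pixel ratio of two aligned channels
#'
#' @param numerator,denominator numeric matrices of equal dimension.
#' @param mask optional logical mask; pixels outside are `NA`.
#' @param floor positive floor on the denominator; pixels at or below it are
#'   undefined (`NA`) and excluded from downstream bins.
#' @return Matrix of ratios with `NA` where undefined.
#' @export
ratio_image <- function(numerator, denominator, mask = NULL, floor = 1e-6) {
  stopifnot(all(dim(numerator) == dim(denominator)), floor > 0)
  valid <- denominator > floor
  if (!is.null(mask)) valid <- valid & mask
  if (!any(valid)) stop("denominator is at or below the floor everywhere")
  out <- matrix(NA_real_, nrow(numerator), ncol(numerator))
  out[valid] <- numerator[valid] / denominator[valid]
  out
}

#' Bin a signal into 20 equal front-to-back segments
#'
#' Partitions the mask (or ring) pixels into `n_bins` equal-width intervals
#' of the normalized axial coordinate and averages the valid (non-`NA`)
#' signal per bin. Bins that contain mask pixels but no valid signal are
#' linearly interpolated from the nearest non-empty neighbours and flagged.
#'
#' @param values numeric matrix of the signal (e.g. a [ratio_image()]).
#' @param mask logical mask to bin over (cell mask, or ring mask for
#'   peripheral signals).
#' @param axis an [find_front()] axis frame; its `p` must cover the mask
#'   (ring pixels outside the cell use clipped projection, recomputed here).
#' @param n_bins number of segments (default 20).
#' @param normalize divide the profile by the mean valid signal over the
#'   whole mask (scale-free profiles for cross-cell averaging).
#' @return A `gradient_profile` list: `mean` (length `n_bins`, front to
#'   back), `n_pixels` (partition counts, summing to the mask area),
#'   `n_valid` (pixels entering each mean), `interpolated` (logical),
#'   `normalized`.
#' @export
bin_profile <- function(values, mask, axis, n_bins = 20, normalize = FALSE) {
  stopifnot(all(dim(values) == dim(mask)))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  # recompute clipped projection so ring pixels slightly outside the cell
  # mask still get a coordinate
  proj <- ((idx[, 1] - axis$front[1]) * axis$axis[1] +
             (idx[, 2] - axis$front[2]) * axis$axis[2]) / axis$length_px
  p <- pmin(pmax(proj, 0), 1)
  bin <- pmin(floor(p * n_bins), n_bins - 1L) + 1L
  v <- values[idx]
  ok <- !is.na(v)
  n_pixels <- tabulate(bin, nbins = n_bins)
  n_valid <- tabulate(bin[ok], nbins = n_bins)
  sums <- vapply(seq_len(n_bins),
                 function(k) sum(v[ok & bin == k]), numeric(1))
  means <- ifelse(n_valid > 0, sums / pmax(n_valid, 1), NA_real_)
  interpolated <- n_valid == 0
  if (any(interpolated)) {
    if (all(interpolated)) stop("no valid signal in any bin")
    means <- interp_na(means)
  }
  if (normalize) means <- means / mean(v[ok])
  structure(list(mean = means, n_pixels = n_pixels, n_valid = n_valid,
                 interpolated = interpolated, normalized = normalize),
            class = "gradient_profile")
}

# linear interpolation of NA runs from nearest non-NA neighbours,
# extending flat at the ends
interp_na <- function(x) {
  ok <- which(!is.na(x))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Assemble per-frame profiles into a kymograph
#'
#' @param profiles list of [bin_profile()] results (or numeric vectors) of
#'   equal length, one per time point; `NULL` entries mark missing frames.
#' @return A `kymograph` list: `matrix` (`n_bins` rows by `T` columns;
#'   column `t` is the profile at frame `t`, `NA` for missing frames),
#'   `mean` profile across available frames, `sd`, `se`, and
#'   `missing_frames`.
#' @export
assemble_kymograph <- function(profiles) {
  vecs <- lapply(profiles, function(pr) {
    if (is.null(pr)) NULL else if (inherits(pr, "gradient_profile")) pr$mean
    else as.numeric(pr)
  })
  lens <- unique(vapply(Filter(Negate(is.null), vecs), length, integer(1)))
  if (length(lens) != 1) stop("profiles must have equal length")
  n_bins <- lens
  mat <- matrix(NA_real_, n_bins, length(vecs))
  for (t in seq_along(vecs)) if (!is.null(vecs[[t]])) mat[, t] <- vecs[[t]]
  missing <- which(vapply(vecs, is.null, logical(1)))
  avail <- setdiff(seq_along(vecs), missing)
  mu <- rowMeans(mat[, avail, drop = FALSE])
  sd_ <- apply(mat[, avail, drop = FALSE], 1, stats::sd)
  structure(list(matrix = mat, mean = mu, sd = sd_,
                 se = sd_ / sqrt(length(avail)),
                 missing_frames = missing),
            class = "kymograph")
}

#' Polarity-steepness scores of a front-to-back profile
#'
#' Two definitions: `score20` normalizes the absolute difference of the
#' front-20% and back-20% bin means to the back-20% mean; `ratio50` is the
#' front-half mean over the back-half mean (optionally reported on a log2
#' scale). Both are invariant to global intensity scaling.
#'
#' @param profile a [bin_profile()] result or numeric front-to-back vector.
#' @return List `score20, ratio50, log2_ratio50`.
#' @export
steepness <- function(profile) {
  v <- if (inherits(profile, "gradient_profile")) profile$mean else
    as.numeric(profile)
  n <- length(v)
  k <- ceiling(0.2 * n)
  front20 <- mean(v[seq_len(k)])
  back20 <- mean(v[seq.int(n - k + 1L, n)])
  if (!is.finite(back20) || back20 == 0) {
    stop("score20 is undefined: zero back-segment mean")
  }
  half <- n %/% 2
  front50 <- mean(v[seq_len(half)])
  back50 <- mean(v[seq.int(n - half + 1L, n)])
  if (!is.finite(back50) || back50 <= 0 || front50 <= 0) {
    stop("ratio50 requires positive half means")
  }
  list(score20 = abs(front20 - back20) / back20,
       ratio50 = front50 / back50,
       log2_ratio50 = log2(front50 / back50))
}

#' Front and back segment means of a profile
#'
#' Means over the first and last `ceiling(fraction * n_bins)` bins, exported
#' for downstream front-versus-back hypothesis tests.
#'
#' @param profile a [bin_profile()] result or numeric vector.
#' @param fraction fraction of bins at each end, in `(0, 0.5]`.
#' @return List `front, back`.
#' @export
front_back_summary <- function(profile, fraction = 0.2) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]")
  }
  v <- if (inherits(profile, "gradient_profile")) profile$mean else
    as.numeric(profile)
  n <- length(v)
  k <- ceiling(fraction * n)
  list(front = mean(v[seq_len(k)]), back = mean(v[seq.int(n - k + 1L, n)]))
}

#' Contact growth-rate curve and front/back slopes
#'
#' Because contacts are stationary in the lab frame, a punctum born near the
#' front drifts backwards through the normalized coordinate `p` as the cell
#' migrates; its signal along `p` traces the local growth rate. This takes
#' per-punctum observations `(p, ratio)`, restricts to the cohort of tracks
#' first seen near the front (`first p <= birth_p_max`, emulating a region
#' of interest placed near the front that moves towards the back), averages
#' the ratio in `p` bins, and fits separate first-order polynomials to the
#' binned curve on the front window (`p` in `front_window`) and the back
#' window (`p` from 0.5 to the position of the maximal average signal),
#' weighted by per-bin observation counts. The per-bin average is a median
#' by default: occasional detections that swallow a close neighbour carry a
#' mass error proportional to the local mass, which would otherwise inflate
#' the back slope specifically.
#'
#' @param obs data frame with columns `track_id, p, ratio` (one row per
#'   punctum observation).
#' @param n_bins bins over `[0, 1]` for the averaged curve (default 20).
#' @param front_window front fitting window on `p` (default `c(0.2, 0.5)`).
#' @param birth_p_max cohort cut: only tracks whose first observation lies
#'   at `p <=` this value are used (default 0.25).
#' @param complete_min_p tracks must also be observed out to at least this
#'   `p` (default 0.85). Without this, observations at large `p` come only
#'   from the earliest-born (hence longest-grown) puncta, which steepens
#'   the averaged curve's back segment regardless of the true growth field;
#'   requiring full traversal keeps the cohort composition constant across
#'   the fitted range. Set to 0 to disable.
#' @param min_p_range minimal spanned `p` range; below it the cell has not
#'   moved enough and the curve degenerates (error).
#' @param stat per-bin averaging statistic, `"median"` (default, robust to
#'   merged-detection outliers) or `"mean"`.
#' @return List `curve` (data frame `p_mid, mean_ratio, n`), `slope_front`,
#'   `slope_back`, `slope_ratio` (back/front), `p_argmax`, `n_obs`.
#' @export
growth_rate_curve <- function(obs, n_bins = 20, front_window = c(0.2, 0.5),
                              birth_p_max = 0.25, complete_min_p = 0.85,
                              min_p_range = 0.3, stat = c("median", "mean")) {
  stat_fun <- switch(match.arg(stat), median = stats::median, mean = mean)
  stopifnot(all(c("track_id", "p", "ratio") %in% names(obs)))
  obs <- obs[order(obs$track_id), , drop = FALSE]
  first_p <- tapply(obs$p, obs$track_id, function(p) p[1])
  max_p <- tapply(obs$p, obs$track_id, max)
  cohort <- names(first_p)[first_p <= birth_p_max & max_p >= complete_min_p]
  o <- obs[as.character(obs$track_id) %in% cohort, , drop = FALSE]
  if (nrow(o) == 0) stop("no tracks start within birth_p_max of the front")
  if (diff(range(o$p)) < min_p_range) {
    stop("insufficient p range: the cell has not migrated far enough")
  }
  bin <- pmin(floor(o$p * n_bins), n_bins - 1L) + 1L
  curve <- data.frame(
    p_mid = (seq_len(n_bins) - 0.5) / n_bins,
    mean_ratio = vapply(seq_len(n_bins), function(k) {
      v <- o$ratio[bin == k]
      if (length(v) > 0) stat_fun(v) else NA_real_
    }, numeric(1)),
    n = tabulate(bin, nbins = n_bins))
  occupied <- which(!is.na(curve$mean_ratio))
  p_argmax <- curve$p_mid[occupied[which.max(curve$mean_ratio[occupied])]]
  if (p_argmax <= 0.5) stop("back window is empty: signal peaks before p = 0.5")

  fit_window <- function(lo, hi) {
    cc <- curve[curve$p_mid >= lo & curve$p_mid <= hi & curve$n > 0 &
                  !is.na(curve$mean_ratio), ]
    if (nrow(cc) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(mean_ratio ~ p_mid, data = cc,
                                 weights = cc$n))[2])
  }
  slope_front <- fit_window(front_window[1], front_window[2])
  slope_back <- fit_window(0.5, p_argmax)
  list(curve = curve, slope_front = slope_front, slope_back = slope_back,
       slope_ratio = slope_back / slope_front, p_argmax = p_argmax,
       n_obs = nrow(o))
}
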
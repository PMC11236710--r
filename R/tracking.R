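#' Link per-frame observations into tracks by greedy mutual nearest neighbour
#'
#' Frame-to-frame assignment minimizing
#' `cost = distance / max_disp + mass_weight * |delta mass| / mean mass`,
#' where the mean mass is taken over both frames' observations. Pairs
#' farther apart than `max_disp` are never linked; assignments are taken
#' greedily in order of increasing cost (equivalent to mutual nearest
#' neighbours for well-separated objects). Unmatched observations start new
#' tracks. Observations are put into a canonical order within each frame
#' before matching, so the result is invariant to row permutations; cost
#' ties are broken deterministically by that order.
#'
#' @param observations data frame with columns `frame, y, x, mass`
#'   (additional columns are carried through).
#' @param max_disp maximum linking displacement in pixels.
#' @param mass_weight weight of the mass term (0 disables it).
#' @return The observation data frame with a `track_id` column, ordered by
#'   `track_id` then `frame`.
#' @export
link_observations <- function(observations, max_disp, mass_weight = 1) {
  stopifnot(all(c("frame", "y", "x", "mass") %in% names(observations)),
            max_disp > 0, mass_weight >= 0)
  obs <- observations[order(observations$frame, observations$x,
                            observations$y, observations$mass), , drop = FALSE]
  frames <- sort(unique(obs$frame))
  obs$track_id <- NA_integer_
  next_id <- 1L
  prev_idx <- which(obs$frame == frames[1])
  obs$track_id[prev_idx] <- seq.int(next_id, length.out = length(prev_idx))
  next_id <- next_id + length(prev_idx)

  for (fi in seq_along(frames)[-1]) {
    cur_idx <- which(obs$frame == frames[fi])
    linked <- rep(FALSE, length(cur_idx))
    if (length(prev_idx) > 0 && length(cur_idx) > 0 &&
        frames[fi] == frames[fi - 1] + 1L) {
      d <- sqrt(outer(obs$y[prev_idx], obs$y[cur_idx], "-")^2 +
                  outer(obs$x[prev_idx], obs$x[cur_idx], "-")^2)
      mbar <- mean(c(obs$mass[prev_idx], obs$mass[cur_idx]))
      if (!is.finite(mbar) || mbar <= 0) mbar <- 1
      cost <- d / max_disp +
        mass_weight * abs(outer(obs$mass[prev_idx], obs$mass[cur_idx], "-")) / mbar
      cost[d > max_disp] <- Inf
      # greedy: repeatedly take the cheapest remaining pair
      repeat {
        j <- which.min(cost)
        if (length(j) == 0 || !is.finite(cost[j])) break
        pi_ <- (j - 1L) %% length(prev_idx) + 1L
        ci <- (j - 1L) %/% length(prev_idx) + 1L
        obs$track_id[cur_idx[ci]] <- obs$track_id[prev_idx[pi_]]
        linked[ci] <- TRUE
        cost[pi_, ] <- Inf
        cost[, ci] <- Inf
      }
    }
    new_ <- which(!linked)
    if (length(new_) > 0) {
      obs$track_id[cur_idx[new_]] <- seq.int(next_id, length.out = length(new_))
      next_id <- next_id + length(new_)
    }
    prev_idx <- cur_idx
  }
  obs <- obs[order(obs$track_id, obs$frame), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Link cell observations into cell tracks
#'
#' Thin wrapper over [link_observations()] with cell-scale defaults; the
#' nuclear (or cell) mass is used as a constant identity metric to
#' disambiguate crossings.
#'
#' @param observations data frame `frame, y, x, mass` (one row per detected
#'   cell per frame).
#' @param max_disp maximum displacement per frame, pixels.
#' @param mass_weight weight of the mass term (default 1).
#' @return Tracked data frame with `track_id` (see [link_observations()]).
#' @export
link_cells <- function(observations, max_disp, mass_weight = 1) {
  link_observations(observations, max_disp = max_disp, mass_weight = mass_weight)
}

#' Cell speed as total travelled distance over travelling time
#'
#' @param track data frame `frame, y, x` of one track (pixels).
#' @param pixel_size pixel size in micrometres.
#' @param frame_interval frame interval in seconds.
#' @return Speed in micrometres per minute.
#' @export
compute_speed <- function(track, pixel_size, frame_interval) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2) stop("speed is undefined for a track of length < 2")
  path <- sum(sqrt(diff(track$y)^2 + diff(track$x)^2)) * pixel_size
  minutes <- (track$frame[nrow(track)] - track$frame[1]) * frame_interval / 60
  path / minutes
}

#' Ensemble mean squared displacement from each track's origin
#'
#' `MSD(lag) = mean over tracks of |pos(t0 + lag) - pos(t0)|^2`, where `t0`
#' is each track's own first frame; the average is across tracks (not
#' time-averaged within tracks).
#'
#' @param tracks data frame `track_id, frame, y, x` (pixels).
#' @param pixel_size pixel size in micrometres.
#' @param frame_interval frame interval in seconds.
#' @param max_lag maximum lag in frames (default: longest track span).
#' @return Data frame `lag_frames, lag_s, msd_um2, n, se`; lags covered by
#'   no track have `NA` msd.
#' @export
compute_msd <- function(tracks, pixel_size, frame_interval, max_lag = NULL) {
  stopifnot(all(c("track_id", "frame", "y", "x") %in% names(tracks)))
  by_track <- split(tracks[, c("frame", "y", "x")], tracks$track_id)
  if (is.null(max_lag)) {
    max_lag <- max(vapply(by_track, function(tr) diff(range(tr$frame)),
                          numeric(1)))
  }
  sq <- vector("list", length(by_track))
  for (i in seq_along(by_track)) {
    tr <- by_track[[i]]
    tr <- tr[order(tr$frame), , drop = FALSE]
    lag <- tr$frame - tr$frame[1]
    keep <- lag >= 1 & lag <= max_lag
    if (!any(keep)) next
    sq[[i]] <- data.frame(
      lag = lag[keep],
      d2 = ((tr$y[keep] - tr$y[1])^2 + (tr$x[keep] - tr$x[1])^2) * pixel_size^2)
  }
  all_d2 <- do.call(rbind, sq)
  out <- data.frame(lag_frames = seq_len(max_lag))
  out$lag_s <- out$lag_frames * frame_interval
  if (is.null(all_d2)) {
    out$msd_um2 <- NA_real_; out$n <- 0L; out$se <- NA_real_
    return(out)
  }
  agg_n <- tabulate(all_d2$lag, nbins = max_lag)
  agg_sum <- vapply(seq_len(max_lag),
                    function(k) sum(all_d2$d2[all_d2$lag == k]), numeric(1))
  agg_sd <- vapply(seq_len(max_lag), function(k) {
    v <- all_d2$d2[all_d2$lag == k]
    if (length(v) > 1) stats::sd(v) else NA_real_
  }, numeric(1))
  out$msd_um2 <- ifelse(agg_n > 0, agg_sum / agg_n, NA_real_)
  out$n <- agg_n
  out$se <- agg_sd / sqrt(pmax(agg_n, 1))
  out
}

#' Fit migration direction and detect reversals from a centroid track
#'
#' Centroids are smoothed with a centred moving average and the stripe-axis
#' coordinate is fitted by a first-order polynomial in time; the sign of the
#' slope gives the direction. The significance of the slope is assessed on
#' the unsmoothed coordinates (the moving average would inflate the test);
#' a non-significant slope is labelled `stalled`. Reversal events are
#' reported where the sign of the smoothed frame-to-frame displacement
#' flips and the new sign persists for at least `persist_k` frames.
#'
#' @param track data frame `frame, y, x` (pixels).
#' @param smooth_window moving-average window in frames (odd; default 5).
#' @param persist_k frames a new direction must persist to count as a
#'   reversal (default 5).
#' @param alpha significance level of the slope test (default 0.05).
#' @return List with `slope` (px/frame along x), `direction` (-1, 0 or 1; 0
#'   when stalled), `stalled`, `p_value`, and `reversals` (frame indices).
#' @export
fit_direction <- function(track, smooth_window = 5, persist_k = 5,
                          alpha = 0.05) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < max(smooth_window, 3)) {
    stop("track shorter than the smoothing window")
  }
  xs <- as.numeric(stats::filter(track$x, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  fit <- stats::lm(x ~ frame, data = track)
  sm <- summary(fit)$coefficients
  slope <- sm["frame", "Estimate"]
  p_value <- sm["frame", "Pr(>|t|)"]
  stalled <- !is.finite(p_value) || p_value > alpha

  # reversal detection on the smoothed series
  dx <- diff(xs)
  sgn <- sign(dx)
  sgn[is.na(sgn)] <- 0
  runs <- rle(sgn)
  keep <- runs$values != 0 & runs$lengths >= persist_k
  dirs <- runs$values[keep]
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)[keep]
  reversals <- integer(0)
  if (length(dirs) > 1) {
    flip <- which(dirs[-1] != dirs[-length(dirs)])
    reversals <- track$frame[pmin(starts[flip + 1], nrow(track))]
  }
  list(slope = slope,
       direction = if (stalled) 0L else as.integer(sign(slope)),
       stalled = stalled, p_value = p_value, reversals = reversals)
}
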
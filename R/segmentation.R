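#' Detect nuclei with a Laplacian-of-Gaussian blob detector
#'
#' Convolves the frame with a Laplacian-of-Gaussian kernel matched to the
#' expected nuclear scale, thresholds the blob response, and reports one
#' observation per response maximum. Touching nuclei whose joint component
#' contains more than one maximum, is strongly elongated, or is far larger
#' than a single nucleus are flagged `ambiguous`.
#'
#' @param img single-channel 2D numeric matrix.
#' @param pixel_size pixel size in micrometres.
#' @param scale_range expected nuclear diameter range in micrometres.
#' @param min_area minimum component area in pixels.
#' @return Data frame with one row per detection:
#'   `id, y, x, area, mean_intensity, mass, ambiguous`. Centroids are
#'   intensity-weighted on the background-subtracted image; `mass` is the
#'   background-subtracted integrated intensity (intensity times area).
#'   Empty images give zero rows.
#' @export
segment_nuclei <- function(img, pixel_size, scale_range = c(6, 14),
                           min_area = 20) {
  stopifnot(is.matrix(img), pixel_size > 0)
  out0 <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                     area = numeric(0), mean_intensity = numeric(0),
                     mass = numeric(0), ambiguous = logical(0))
  rng <- range(img)
  if (diff(rng) <= 0) return(out0)

  bg <- background_mode(img)
  # blob radius R -> optimal LoG sigma = R / sqrt(2)
  sigma <- mean(scale_range) / 2 / pixel_size / sqrt(2)
  kern <- log_kernel(sigma, max_halfwidth = (min(dim(img)) - 1L) %/% 2L)
  resp <- EBImage::filter2(img, -kern)          # positive on bright blobs

  fg <- resp > 0.2 * max(resp) & img > bg$mode + 2 * bg$mad
  if (!any(fg)) return(out0)
  lbl <- EBImage::bwlabel(fg * 1)
  areas <- tabulate(lbl[lbl > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(out0)

  # local maxima of the response inside the foreground
  mx <- EBImage::dilate(resp, ebi_brush(max(1L, round(sigma))))
  is_max <- fg & resp >= mx - 1e-12

  single_area <- pi * (max(scale_range) / 2 / pixel_size)^2
  rows <- list()
  nid <- 0L
  for (k in keep) {
    comp <- which(lbl == k, arr.ind = TRUE)
    comp_max <- comp[is_max[comp], , drop = FALSE]
    if (nrow(comp_max) == 0) comp_max <- comp[which.max(resp[comp]), , drop = FALSE]
    # merge maxima closer than sigma (plateaus)
    comp_max <- merge_close_points(comp_max, sigma)
    n_max <- nrow(comp_max)
    ambiguous <- n_max > 1 || areas[k] > 2 * single_area ||
      component_elongation(comp) > 1.4
    w <- img[comp] - bg$mode
    if (n_max == 1) {
      ctr <- weighted_centroid(comp, w)
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = nid, y = ctr["y"], x = ctr["x"], area = nrow(comp),
        mean_intensity = mean(w), mass = sum(w), ambiguous = ambiguous)
    } else {
      # split pixels by nearest maximum
      d2 <- outer(comp[, 1], comp_max[, 1], "-")^2 +
        outer(comp[, 2], comp_max[, 2], "-")^2
      assign <- max.col(-d2)
      for (j in seq_len(n_max)) {
        sel <- assign == j
        if (sum(sel) == 0) next
        ctr <- weighted_centroid(comp[sel, , drop = FALSE], w[sel])
        nid <- nid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = nid, y = ctr["y"], x = ctr["x"], area = sum(sel),
          mean_intensity = mean(w[sel]), mass = sum(w[sel]),
          ambiguous = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

log_kernel <- function(sigma, max_halfwidth = Inf) {
  w <- min(ceiling(4 * sigma), max_halfwidth)
  g <- seq(-w, w)
  gs <- exp(-g^2 / (2 * sigma^2))
  G <- outer(gs, gs)
  G <- G / sum(G)
  r2 <- outer(g^2, g^2, "+")
  k <- G * (r2 - 2 * sigma^2) / sigma^4
  k - mean(k)  # zero-mean so flat regions give zero response
}

# sqrt of the principal-axis variance ratio of a pixel set; ~1 for a disk
component_elongation <- function(idx) {
  if (nrow(idx) < 4) return(1)
  v <- stats::cov(idx)
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(Inf)
  sqrt(ev[1] / ev[2])
}

merge_close_points <- function(pts, min_dist) {
  if (nrow(pts) <= 1) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(pts)) {
      if (keep[j] &&
          sum((pts[i, ] - pts[j, ])^2) < min_dist^2) keep[j] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

#' Segment whole cells from a plasma-membrane marker channel
#'
#' Thresholds with a modified Otsu: the threshold is computed on
#' log1p-transformed, background-mode-subtracted intensities and combined
#' with a robust noise floor (two MADs above the background mode). The log
#' transform compresses the bright cell-body range so the Otsu split lands
#' below dim lamellipodia and keeps them attached. Masks are hole-filled;
#' objects
#' below `min_area`, touching the image border, or failing the isolation
#' test (masks overlapping after dilation) are discarded.
#'
#' @param img single-channel 2D numeric matrix (PM marker).
#' @param pixel_size pixel size in micrometres.
#' @param min_area minimum object area in pixels.
#' @param isolation_dist_um isolation distance: cells whose masks come
#'   within twice this distance of each other are discarded.
#' @param discard_border drop masks touching the image border.
#' @return List of per-cell observations, each a list with `mask` (logical
#'   full-frame matrix, one connected component), `centroid` `(y, x)`,
#'   `area` (px) and `mass` (background-subtracted integrated intensity).
#'   Empty list (with a warning) when nothing is above threshold.
#' @export
segment_cell_pm <- function(img, pixel_size, min_area = 100,
                            isolation_dist_um = 1.2, discard_border = TRUE) {
  stopifnot(is.matrix(img), pixel_size > 0)
  bg <- background_mode(img)
  coarse <- img > bg$mode + 2 * max(bg$mad, .Machine$double.eps)
  if (!any(coarse)) {
    warning("no foreground above the coarse background threshold")
    return(list())
  }
  thr <- expm1(otsu_threshold(log1p(pmax(img - bg$mode, 0))))
  fg <- (img - bg$mode) > thr & coarse
  if (!any(fg)) {
    warning("no foreground above the Otsu threshold")
    return(list())
  }
  fg <- EBImage::fillHull(EBImage::bwlabel(fg * 1)) > 0
  lbl <- EBImage::bwlabel(fg * 1)
  n <- max(lbl)
  areas <- tabulate(lbl[lbl > 0], nbins = n)
  keep <- which(areas >= min_area)

  if (discard_border) {
    border_labels <- unique(c(lbl[1, ], lbl[nrow(lbl), ], lbl[, 1], lbl[, ncol(lbl)]))
    keep <- setdiff(keep, border_labels)
  }

  # isolation: dilated masks must not touch another kept mask
  r <- max(1L, round(isolation_dist_um / pixel_size))
  if (length(keep) > 1) {
    dil <- lapply(keep, function(k) ebi_dilate(lbl == k, r))
    bad <- logical(length(keep))
    for (i in seq_along(keep)) {
      others <- Reduce(`|`, dil[-i], matrix(FALSE, nrow(lbl), ncol(lbl)))
      if (any(dil[[i]] & others)) bad[i] <- TRUE
    }
    keep <- keep[!bad]
  }

  lapply(keep, function(k) {
    mask <- lbl == k
    idx <- which(mask, arr.ind = TRUE)
    w <- img[idx] - bg$mode
    ctr <- weighted_centroid(idx, w)
    list(mask = mask, centroid = ctr, area = nrow(idx), mass = sum(w))
  })
}

#' Peripheral ring mask of a cell
#'
#' Band of the stated physical width straddling the mask boundary, extending
#' half the width inward and half outward (computed from Euclidean distance
#' maps). A width of one pixel degenerates to the one-pixel inner boundary.
#'
#' @param mask logical cell mask.
#' @param width_um band width in micrometres (default 3).
#' @param pixel_size pixel size in micrometres.
#' @return Logical matrix of the ring (clipped at image borders).
#' @export
ring_mask <- function(mask, width_um = 3, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  w_px <- width_um / pixel_size
  if (w_px < 1) stop("ring width is below one pixel")
  # pad with background so the image border acts as a boundary for masks
  # that reach it (the ring is then clipped at the frame)
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  din <- as.matrix(EBImage::distmap(pad * 1))
  dout <- as.matrix(EBImage::distmap((!pad) * 1))
  # pixel centers sit half a pixel from the mask edge; the boundary row
  # counts towards the inner half of the band
  band <- (pad & din <= w_px / 2 + 0.5) | (!pad & dout <= w_px / 2)
  band[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}
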
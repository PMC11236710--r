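# Small wrappers around EBImage morphology so the rest of the package can
# work with plain logical Y-by-X matrices.

ebi_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

ebi_erode <- function(mask, r) {
  if (r < 1) return(mask)
  EBImage::erode(mask * 1, ebi_brush(r)) > 0.5
}

ebi_dilate <- function(mask, r) {
  if (r < 1) return(mask)
  EBImage::dilate(mask * 1, ebi_brush(r)) > 0.5
}

# Otsu threshold of a numeric vector (EBImage otsu on a 1-column image,
# rescaled to [0, 1]); returns a threshold on the original scale.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(Inf)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  img <- EBImage::Image(matrix((v - lo) / (hi - lo), ncol = 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}

# Mode of the background intensity distribution, from a kernel density
# estimate. Robust MAD around that mode.
background_mode <- function(img) {
  v <- as.numeric(img)
  d <- stats::density(v, n = 512)
  mode <- d$x[which.max(d$y)]
  list(mode = mode, mad = stats::mad(v, center = mode))
}

# weighted centroid (y, x) of a set of pixels
weighted_centroid <- function(idx, w) {
  w <- pmax(w, 0)
  if (sum(w) <= 0) w <- rep(1, nrow(idx))
  c(y = sum(idx[, 1] * w) / sum(w), x = sum(idx[, 2] * w) / sum(w))
}
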
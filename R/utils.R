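# Internal helpers shared across assay modules.

# Otsu threshold on a vector of intensities. Values are range-normalised to
# [0,1] so the 256-level histogram spans the observed dynamic range; the
# returned threshold is on the original intensity scale. Pixels are foreground
# when strictly greater than the threshold.
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  r <- range(v)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("degenerate threshold: intensities are constant", call. = FALSE)
  }
  img <- EBImage::Image(matrix((v - r[1]) / (r[2] - r[1]), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  r[1] + thr * (r[2] - r[1])
}

# Exact Euclidean-disc dilation via the distance transform: a pixel belongs to
# the dilated mask iff its distance to the nearest mask pixel is <= radius.
disc_dilate <- function(mask, radius_px) {
  mask <- mask_values(mask)
  if (!any(mask)) stop("cannot dilate an empty mask", call. = FALSE)
  if (radius_px <= 0) return(mask)
  d <- EBImage::distmap(EBImage::Image(1 - mask))
  m <- as.matrix(EBImage::imageData(d)) <= radius_px
  dim(m) <- dim(mask)
  m
}

# Keep only connected components of at least min_px pixels (8-connectivity).
filter_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

largest_component <- function(mask) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0) stop("segmentation produced an empty mask", call. = FALSE)
  matrix(lab == which.max(sizes), nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  m <- as.matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))) > 0
  dim(m) <- dim(mask)
  m
}

# Even-odd rasterisation of a polygon given vertices as (row, col) in pixel
# units (1-based pixel centres). Pixels whose centre lies on an edge are
# included (tolerance nudge), so a hull always contains its defining pixels.
rasterize_polygon <- function(vertices_rc, dim_rc) {
  nr <- dim_rc[1]; nc <- dim_rc[2]
  vr <- vertices_rc[, 1]; vcol <- vertices_rc[, 2]
  n <- length(vr)
  pr <- rep(seq_len(nr), times = nc)
  pc <- rep(seq_len(nc), each = nr)
  inside <- logical(nr * nc)
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    yi <- vr[i]; yj <- vr[j]; xi <- vcol[i]; xj <- vcol[j]
    crosses <- ((yi > pr - eps) != (yj > pr - eps))
    if (any(crosses)) {
      xcross <- (xj - xi) * (pr[crosses] - yi) / (yj - yi) + xi
      inside[crosses] <- xor(inside[crosses], pc[crosses] < xcross + eps)
    }
    j <- i
  }
  matrix(inside, nr, nc)
}

# Filled convex hull of a logical mask, as a logical mask of the same shape.
convex_hull_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no convex hull", call. = FALSE)
  if (nrow(idx) < 3) return(mask)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hull <- rasterize_polygon(idx[h, , drop = FALSE], dim(mask))
  hull | mask
}

# 2-D Gaussian spots added onto an image. centres_rc in fractional pixel
# coordinates (1-based), amplitude = expected total photons per spot.
render_spots <- function(img, centres_rc, amplitudes, sd_px = 1.3) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sd_px)
  amplitudes <- rep_len(amplitudes, nrow(centres_rc))
  for (k in seq_len(nrow(centres_rc))) {
    r0 <- centres_rc[k, 1]; c0 <- centres_rc[k, 2]
    rows <- max(1L, floor(r0 - w)):min(nr, ceiling(r0 + w))
    cols <- max(1L, floor(c0 - w)):min(nc, ceiling(c0 + w))
    if (length(rows) == 0 || length(cols) == 0) next
    g <- outer(
      exp(-(rows - r0)^2 / (2 * sd_px^2)),
      exp(-(cols - c0)^2 / (2 * sd_px^2))
    )
    img[rows, cols] <- img[rows, cols] + amplitudes[k] * g / (2 * pi * sd_px^2)
  }
  img
}

# Mark pixels hit by a polyline (vertices in fractional pixel coords, 1-based),
# sampling every `step` px along each edge and stamping a small disc.
rasterize_polyline <- function(mask, verts_rc, radius_px = 1, step = 0.4) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts_r <- numeric(0); pts_c <- numeric(0)
  for (i in seq_len(nrow(verts_rc) - 1L)) {
    d <- sqrt(sum((verts_rc[i + 1L, ] - verts_rc[i, ])^2))
    n <- max(2L, ceiling(d / step) + 1L)
    a <- seq(0, 1, length.out = n)
    pts_r <- c(pts_r, verts_rc[i, 1] + a * (verts_rc[i + 1L, 1] - verts_rc[i, 1]))
    pts_c <- c(pts_c, verts_rc[i, 2] + a * (verts_rc[i + 1L, 2] - verts_rc[i, 2]))
  }
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, ]
  for (j in seq_len(nrow(offs))) {
    rr <- round(pts_r) + offs$dr[j]
    cc <- round(pts_c) + offs$dc[j]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

# Format numbers for CSV output: full double precision, locale-independent.
format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}
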
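#' Segment the nucleus inside a coarse ROI
#'
#' Thresholds the nucleus channel inside a user-supplied coarse region of
#' interest with an automatically chosen bimodal (Otsu) threshold, keeps the
#' largest connected component and fills its holes. The coarse ROI plays the
#' role of the manual nucleus selection of the original assay; the threshold
#' refines it to the actual stained nucleus.
#'
#' @param nucleus_channel image plane (matrix) of the nuclear stain.
#' @param coarse_roi [BinaryMask] (or logical matrix) enclosing the nucleus.
#' @return a [BinaryMask] with provenance `"nucleus"`.
#' @export
nucleus_mask <- function(nucleus_channel, coarse_roi) {
  roi <- mask_values(coarse_roi)
  if (!any(roi)) stop("coarse ROI is empty", call. = FALSE)
  stopifnot(all(dim(roi) == dim(nucleus_channel)))
  thr <- otsu_threshold(nucleus_channel[roi])
  mask <- (nucleus_channel > thr) & roi
  if (!any(mask)) stop("segmentation produced an empty mask", call. = FALSE)
  mask <- fill_holes(largest_component(mask))
  BinaryMask(mask, "nucleus")
}

#' Extend a mask outward by a fixed distance
#'
#' Morphological dilation with a Euclidean disc of radius `distance_px`,
#' computed exactly through the distance transform, so the output contains
#' every pixel within that distance of the input. Used for the 10-pixel
#' outward extension of the nucleus that defines the perinuclear measurement
#' region.
#'
#' @param mask [BinaryMask] or logical matrix (non-empty).
#' @param distance_px dilation radius in pixels (>= 0; 0 is the identity).
#' @return a [BinaryMask] with the same provenance.
#' @export
extend_mask <- function(mask, distance_px) {
  stopifnot(distance_px >= 0)
  m <- mask_values(mask)
  if (!any(m)) stop("cannot extend an empty mask", call. = FALSE)
  BinaryMask(disc_dilate(m, distance_px),
             attr(mask, "provenance") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Golgi integrity statistic over a region
#'
#' Computes `SD_i / sqrt(mean)`: the standard deviation of Golgi-channel pixel
#' intensities over the measurement region, normalised by the square root of
#' their mean. For pure shot noise (Poisson counts) this is 1 regardless of
#' intensity, which is what makes the statistic insensitive to staining
#' efficiency and exposure time; a compact perinuclear Golgi drives it well
#' above the shot-noise baseline, a dispersed Golgi pulls it down towards it.
#'
#' @param golgi_channel image plane of the Golgi stain.
#' @param region [BinaryMask] of the measurement region (the dilated nucleus).
#' @param cell_id label carried into the result.
#' @param sd_type `"population"` (divide by N; default — the statistic is a
#'   per-region descriptor, not a sampling estimator) or `"sample"`.
#' @param nucleus_area_px optional pixel count of the nucleus proper, stored
#'   in the result for bookkeeping.
#' @return a `GolgiMeasurement`: list with `cell_id`, `integrity`,
#'   `region_area_px`, `nucleus_area_px`.
#' @export
golgi_integrity <- function(golgi_channel, region, cell_id = "cell",
                            sd_type = c("population", "sample"),
                            nucleus_area_px = NA_integer_) {
  sd_type <- match.arg(sd_type)
  reg <- mask_values(region)
  if (!any(reg)) stop("measurement region is empty", call. = FALSE)
  v <- golgi_channel[reg]
  m <- mean(v)
  if (m <= 0) stop("invalid measurement: mean intensity over region is not positive",
                   call. = FALSE)
  n <- length(v)
  s <- if (sd_type == "population") sqrt(sum((v - m)^2) / n) else stats::sd(v)
  if (n < 2L && sd_type == "sample") s <- 0
  structure(
    list(cell_id = cell_id, integrity = s / sqrt(m), region_area_px = n,
         nucleus_area_px = nucleus_area_px),
    class = "GolgiMeasurement"
  )
}

#' @export
as.data.frame.GolgiMeasurement <- function(x, ...) {
  data.frame(cell_id = x$cell_id, integrity = x$integrity,
             region_area_px = x$region_area_px,
             nucleus_area_px = x$nucleus_area_px, stringsAsFactors = FALSE)
}

#' @export
print.GolgiMeasurement <- function(x, ...) {
  cat(sprintf("GolgiMeasurement %s: integrity %.4f over %d px (nucleus %s px)\n",
              x$cell_id, x$integrity, x$region_area_px,
              ifelse(is.na(x$nucleus_area_px), "?", x$nucleus_area_px)))
  invisible(x)
}

#' Full Golgi dispersion measurement for one cell
#'
#' Pipeline: segment the nucleus inside the coarse ROI, extend it outward
#' (10 px by default), and compute the integrity statistic over the extended
#' region of the Golgi channel.
#'
#' @param stack two-channel [ImageStack]; channel names must include the
#'   `golgi_channel`/`nucleus_channel` labels.
#' @param coarse_roi coarse nucleus ROI mask.
#' @param cell_id label.
#' @param extend_px outward extension of the nucleus mask, pixels.
#' @param region `"full"` (default: the whole dilated nuclear area) or
#'   `"ring"` (the dilated area minus the nucleus proper).
#' @param golgi_channel,nucleus_channel channel names.
#' @inheritParams golgi_integrity
#' @return a `GolgiMeasurement`.
#' @export
golgi_dispersion <- function(stack, coarse_roi, cell_id = "cell",
                             extend_px = 10, region = c("full", "ring"),
                             sd_type = c("population", "sample"),
                             golgi_channel = "golgi",
                             nucleus_channel = "nucleus") {
  region <- match.arg(region)
  nuc <- nucleus_mask(get_plane(stack, 1, nucleus_channel), coarse_roi)
  ext <- extend_mask(nuc, extend_px)
  meas_region <- if (region == "full") mask_values(ext) else
    mask_values(ext) & !mask_values(nuc)
  golgi_integrity(get_plane(stack, 1, golgi_channel),
                  BinaryMask(meas_region, "measurement"),
                  cell_id = cell_id, sd_type = sd_type,
                  nucleus_area_px = sum(mask_values(nuc)))
}

#' Neurite tip accumulation ratio
#'
#' Ratio of the background-subtracted mean fluorescence in a distal (tip)
#' ROI to that in a proximal (shaft) ROI of the same cell. Values above 1
#' indicate accumulation of the marker at the neurite tip.
#'
#' @param img image plane.
#' @param distal_roi,proximal_roi disjoint non-empty ROI masks.
#' @param cell_id label.
#' @param background constant background level subtracted from both means
#'   (default 0: plain ratio).
#' @return a `TipRatio`: list with `cell_id` and `ratio`.
#' @export
tip_accumulation_ratio <- function(img, distal_roi, proximal_roi,
                                   cell_id = "cell", background = 0) {
  d <- mask_values(distal_roi); p <- mask_values(proximal_roi)
  if (!any(d) || !any(p)) stop("ROIs must be non-empty", call. = FALSE)
  if (any(d & p)) stop("distal and proximal ROIs must be disjoint", call. = FALSE)
  pm <- mean(img[p]) - background
  if (pm <= 0) {
    stop("invalid measurement: proximal mean does not exceed background",
         call. = FALSE)
  }
  structure(list(cell_id = cell_id, ratio = (mean(img[d]) - background) / pm),
            class = "TipRatio")
}

#' @export
as.data.frame.TipRatio <- function(x, ...) {
  data.frame(cell_id = x$cell_id, ratio = x$ratio, stringsAsFactors = FALSE)
}

#' @export
print.TipRatio <- function(x, ...) {
  cat(sprintf("TipRatio %s: distal/proximal = %.4f\n", x$cell_id, x$ratio))
  invisible(x)
}
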
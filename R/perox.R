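#' Segment peroxisome puncta by local adaptive thresholding
#'
#' A pixel is kept when its intensity exceeds the local mean over a
#' `window_px` x `window_px` neighbourhood by more than `offset`; connected
#' components smaller than `min_size_px` pixels are discarded as noise.
#'
#' @param frame_561 image plane of the organelle channel.
#' @param window_px odd window edge length, >= 3 and smaller than the image.
#' @param offset intensity offset above the local mean; the default is twice
#'   a robust (MAD) estimate of the background SD.
#' @param min_size_px minimum component size kept.
#' @return a [BinaryMask] with provenance `"peroxisomes"`.
#' @export
segment_peroxisomes <- function(frame_561, window_px = 15L, offset = NULL,
                                min_size_px = 4L) {
  if (window_px %% 2L == 0L || window_px < 3L) {
    stop("window_px must be odd and >= 3", call. = FALSE)
  }
  if (window_px > min(dim(frame_561))) {
    stop("window larger than the image", call. = FALSE)
  }
  if (is.null(offset)) {
    offset <- 2 * stats::mad(frame_561, center = stats::median(frame_561))
  }
  h <- (window_px - 1L) %/% 2L
  scale <- max(frame_561)
  if (scale <= 0) return(BinaryMask(frame_561 > 0, "peroxisomes"))
  # EBImage::thresh keeps pixels above the local boxcar mean plus offset
  img <- EBImage::Image(frame_561 / scale)
  m <- as.matrix(EBImage::imageData(
    EBImage::thresh(img, w = h, h = h, offset = offset / scale))) > 0
  dim(m) <- dim(frame_561)
  BinaryMask(filter_small_components(m, min_size_px), "peroxisomes")
}

#' Peroxisome redistribution time series
#'
#' Per frame: segment the organelle (561) channel, report the mean Euclidean
#' distance of all object pixels from the cell centre (µm) and the mean
#' recruitment (488) channel intensity over the same pixels. Frames whose
#' segmentation is empty yield missing values (never zeros, which would fake
#' inward motion) and are counted in a warning.
#'
#' @param movie two-channel [ImageStack] with channels `"561"` and `"488"`.
#' @param centre_nm cell centre as `c(x, y)` in nm (x along columns).
#' @param window_px,offset,min_size_px passed to [segment_peroxisomes()].
#' @param t_treat_s treatment-addition time marker, seconds.
#' @return a `PeroxTimeSeries`: list with `times_s`, `mean_distance_um`,
#'   `mean_green`, `n_object_px`, `centre_nm`, `t_treat_s`.
#' @export
perox_time_series <- function(movie, centre_nm, window_px = 15L, offset = NULL,
                              min_size_px = 4L, t_treat_s = 0) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!all(c("561", "488") %in% movie$channel_names)) {
    stop("movie must have channels '561' and '488'", call. = FALSE)
  }
  px <- movie$pixel_size_nm
  nf <- n_frames(movie)
  d <- dim(movie$data)
  if (centre_nm[1] < 0 || centre_nm[1] > (d[4] - 1) * px ||
      centre_nm[2] < 0 || centre_nm[2] > (d[3] - 1) * px) {
    stop("centre lies outside the frame", call. = FALSE)
  }
  times <- (seq_len(nf) - 1L) * movie$frame_interval_s
  mean_dist <- rep(NA_real_, nf)
  mean_green <- rep(NA_real_, nf)
  n_px <- integer(nf)
  for (f in seq_len(nf)) {
    mask <- mask_values(segment_peroxisomes(get_plane(movie, f, "561"),
                                            window_px, offset, min_size_px))
    n_px[f] <- sum(mask)
    if (n_px[f] == 0L) next
    idx <- which(mask, arr.ind = TRUE)
    x <- (idx[, 2] - 1) * px
    y <- (idx[, 1] - 1) * px
    mean_dist[f] <- mean(sqrt((x - centre_nm[1])^2 + (y - centre_nm[2])^2)) / 1000
    mean_green[f] <- mean(get_plane(movie, f, "488")[mask])
  }
  if (all(n_px == 0L)) stop("assay failure: no frame contains objects", call. = FALSE)
  if (any(n_px == 0L)) {
    warning(sprintf("%d frame(s) with empty segmentation reported as NA",
                    sum(n_px == 0L)), call. = FALSE)
  }
  structure(
    list(times_s = times, mean_distance_um = mean_dist,
         mean_green = mean_green, n_object_px = n_px,
         centre_nm = centre_nm, t_treat_s = t_treat_s),
    class = "PeroxTimeSeries"
  )
}

#' @export
as.data.frame.PeroxTimeSeries <- function(x, ...) {
  data.frame(t_s = x$times_s, mean_distance_um = x$mean_distance_um,
             mean_green = x$mean_green, n_object_px = x$n_object_px)
}

#' @export
print.PeroxTimeSeries <- function(x, ...) {
  cat(sprintf("PeroxTimeSeries: %d frames, treatment at %g s\n",
              length(x$times_s), x$t_treat_s))
  ok <- is.finite(x$mean_distance_um)
  if (any(ok)) {
    cat(sprintf("  mean distance %.2f -> %.2f um\n",
                x$mean_distance_um[which(ok)[1]],
                x$mean_distance_um[rev(which(ok))[1]]))
  }
  invisible(x)
}

#' Radial-motion slope of a peroxisome series
#'
#' OLS slope of mean object-pixel distance against time over a frame window,
#' the summary used to compare generator ground-truth speeds with recovered
#' outward motion.
#'
#' @param series a `PeroxTimeSeries`.
#' @param from_s,to_s time window (defaults: treatment time to end).
#' @return slope in µm/s.
#' @export
perox_distance_slope <- function(series, from_s = series$t_treat_s,
                                 to_s = Inf) {
  sel <- series$times_s >= from_s & series$times_s <= to_s &
    is.finite(series$mean_distance_um)
  if (sum(sel) < 2L) stop("need >= 2 finite frames in the window", call. = FALSE)
  unname(stats::coef(stats::lm(series$mean_distance_um[sel] ~ series$times_s[sel]))[2])
}
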
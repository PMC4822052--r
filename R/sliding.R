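#' Bleach-correct a time-lapse movie
#'
#' Ratio method: every frame is rescaled so its whole-frame mean intensity
#' equals that of frame 1, removing the global photobleaching trend while
#' preserving relative spatial structure within each frame.
#'
#' @param movie single-channel [ImageStack] with >= 2 frames.
#' @return a bleach-corrected [ImageStack].
#' @export
bleach_correct <- function(movie) {
  stopifnot(inherits(movie, "ImageStack"))
  nf <- n_frames(movie)
  if (nf < 2L) stop("bleach correction needs >= 2 frames", call. = FALSE)
  out <- movie$data
  m0 <- mean(out[1, 1, , ])
  for (f in seq_len(nf)) {
    mf <- mean(out[f, 1, , ])
    if (mf <= 0) stop(sprintf("frame %d has zero mean intensity", f), call. = FALSE)
    out[f, 1, , ] <- out[f, 1, , ] * (m0 / mf)
  }
  ImageStack(out, movie$pixel_size_nm, movie$frame_interval_s,
             movie$channel_names)
}

#' Per-frame motile fraction of photoconverted microtubules
#'
#' Microtubule pixels are detected with a global Otsu threshold computed on
#' frame 1 and applied to every frame (recomputing per frame would conflate
#' residual bleaching with motility, hence bleach correction precedes this
#' step). The initial photoconverted zone is the morphological closing of the
#' filled convex hull of the frame-1 mask, or a user-supplied mask. The
#' motile fraction of frame k is
#' `%MF = 100 * (microtubule pixels outside the zone) / (total microtubule
#' pixels)`; it is 0 at frame 1 by construction.
#'
#' @param movie bleach-corrected single-channel [ImageStack].
#' @param initial_zone optional [BinaryMask] overriding the zone estimated
#'   from frame 1.
#' @param closing_radius_px radius of the disc used to close the hull.
#' @return a `SlidingSeries` with `times_min`, `mf_pct` and `initial_zone`
#'   set; rate fields unset until [sliding_rate()].
#' @export
motile_fraction_series <- function(movie, initial_zone = NULL,
                                   closing_radius_px = 3L) {
  stopifnot(inherits(movie, "ImageStack"))
  nf <- n_frames(movie)
  frame0 <- get_plane(movie, 1, 1)
  thr <- otsu_threshold(frame0)
  mask0 <- frame0 > thr
  if (!any(mask0)) stop("assay failure: empty microtubule mask on frame 1",
                        call. = FALSE)
  if (is.null(initial_zone)) {
    hull <- convex_hull_mask(mask0)
    zone <- as.matrix(EBImage::imageData(EBImage::closing(
      EBImage::Image(hull * 1),
      EBImage::makeBrush(2L * closing_radius_px + 1L, "disc")))) > 0
    dim(zone) <- dim(hull)
    zone <- zone | mask0  # the defining pixels always belong to the zone
  } else {
    zone <- mask_values(initial_zone)
    stopifnot(all(dim(zone) == dim(frame0)))
  }
  mf <- numeric(nf)
  for (f in seq_len(nf)) {
    mk <- get_plane(movie, f, 1) > thr
    total <- sum(mk)
    mf[f] <- if (total == 0L) NA_real_ else 100 * sum(mk & !zone) / total
  }
  structure(
    list(times_min = (seq_len(nf) - 1L) * movie$frame_interval_s / 60,
         mf_pct = mf, initial_zone = BinaryMask(zone, "initial_zone"),
         rate_pct_per_min = NA_real_, window = NULL, r2 = NA_real_,
         n_points = NA_integer_),
    class = "SlidingSeries"
  )
}

# OLS slope and R^2 of y ~ t, closed form. Zero variance in y gives R^2 = 0
# and slope 0 (no motion detected).
ols_slope_r2 <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2)
  syy <- sum((y - yb)^2)
  if (syy <= 0) return(list(slope = 0, r2 = 0))
  b <- sum((t - tb) * (y - yb)) / sxx
  yhat <- yb + b * (t - tb)
  list(slope = b, r2 = 1 - sum((y - yhat)^2) / syy)
}

#' Initial-segment sliding rate
#'
#' Fits ordinary least squares of motile fraction against time over every
#' candidate window anchored at the first frame with at least `min_points`
#' points, and keeps the window with the highest R² — the "initial linear
#' section" of the curve. Ties are broken toward the longer window. A series
#' with zero variance (no motion) gets R² = 0, slope 0 and the full window.
#'
#' @param series a `SlidingSeries` from [motile_fraction_series()].
#' @param min_points minimum window length (default 4).
#' @return the series with `rate_pct_per_min` (% per minute), `window`
#'   (`c(start, end)`, 1-based frame indices), `r2` and `n_points` set.
#' @export
sliding_rate <- function(series, min_points = 4L) {
  stopifnot(inherits(series, "SlidingSeries"))
  ok <- is.finite(series$mf_pct)
  t <- series$times_min[ok]
  y <- series$mf_pct[ok]
  n <- length(y)
  if (n < min_points) {
    stop(sprintf("need >= %d frames with a motile fraction", min_points),
         call. = FALSE)
  }
  # exhaustive scan over anchored windows: highest R2, ties -> longest window
  ks <- min_points:n
  r2s <- vapply(ks, function(k) ols_slope_r2(t[1:k], y[1:k])$r2, numeric(1))
  kbest <- ks[max(which(r2s >= max(r2s) - 1e-12))]
  fit <- ols_slope_r2(t[1:kbest], y[1:kbest])
  series$rate_pct_per_min <- fit$slope
  series$r2 <- fit$r2
  series$window <- c(1L, kbest)
  series$n_points <- kbest
  series
}

#' @export
as.data.frame.SlidingSeries <- function(x, ...) {
  data.frame(t_min = x$times_min, mf_pct = x$mf_pct)
}

#' @export
print.SlidingSeries <- function(x, ...) {
  cat(sprintf("SlidingSeries: %d frames", length(x$times_min)))
  if (is.finite(x$rate_pct_per_min)) {
    cat(sprintf("; rate %.3f %%/min over frames %d-%d (R2 %.3f)",
                x$rate_pct_per_min, x$window[1], x$window[2], x$r2))
  }
  cat("\n")
  invisible(x)
}

#' Full sliding pipeline: bleach correction, motile fraction, rate
#'
#' @param movie raw single-channel time-lapse [ImageStack].
#' @param initial_zone optional user-supplied zone mask.
#' @param min_points minimum fitted-segment length.
#' @return a `SlidingSeries` with rate fields set.
#' @export
sliding_pipeline <- function(movie, initial_zone = NULL, min_points = 4L) {
  sliding_rate(motile_fraction_series(bleach_correct(movie), initial_zone),
               min_points = min_points)
}
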
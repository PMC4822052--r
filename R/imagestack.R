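#' Calibrated image stack
#'
#' Container for a fluorescence image stack indexed `(frame, channel, row,
#' col)` together with its physical calibration. Intensities are photon-scale
#' non-negative values; calibration is always supplied by the caller rather
#' than trusted from file metadata, because TIFF tag dialects vary between
#' acquisition systems.
#'
#' Pixel `(row, col)` (1-based in R) has physical coordinates
#' `x = (col - 1) * pixel_size_nm`, `y = (row - 1) * pixel_size_nm`, i.e. the
#' origin sits at the centre of the top-left pixel and x runs along columns,
#' matching TIFF raster order.
#'
#' @param data numeric array with up to 4 dimensions; missing leading axes are
#'   promoted to singletons so a plain matrix becomes a 1-frame, 1-channel
#'   stack.
#' @param pixel_size_nm length of a pixel edge in nanometres (> 0).
#' @param frame_interval_s seconds between frames; 0 for single images, must
#'   be > 0 when the stack has more than one frame.
#' @param channel_names ordered channel labels; length must equal the channel
#'   dimension. Defaults to `"ch1"`, `"ch2"`, ...
#' @return an object of class `ImageStack`.
#' @export
ImageStack <- function(data, pixel_size_nm, frame_interval_s = 0,
                       channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L) {
    stop("ImageStack data must have at most 4 axes (frame, channel, row, col)",
         call. = FALSE)
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size_nm), length(pixel_size_nm) == 1L,
            pixel_size_nm > 0, frame_interval_s >= 0)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2]) {
    stop("channel_names length must equal the channel dimension", call. = FALSE)
  }
  if (dim(data)[1] > 1L && frame_interval_s <= 0) {
    stop("frame_interval_s must be > 0 for multi-frame stacks", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s,
         channel_names = as.character(channel_names)),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d frame(s) x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel %g nm, frame interval %g s, channels: %s\n",
              x$pixel_size_nm, x$frame_interval_s,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]
n_channels <- function(stack) dim(stack$data)[2]

#' Extract one image plane from a stack
#'
#' @param stack an [ImageStack].
#' @param frame 1-based frame index.
#' @param channel 1-based channel index or a channel name.
#' @return a numeric matrix (row, col).
#' @export
get_plane <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  stack$data[frame, channel, , ]
}

#' Binary image mask
#'
#' A logical grid matching one image plane, carrying a free-text provenance
#' label ("nucleus", "microtubule", "initial_zone", ...).
#'
#' @param values logical matrix (or coercible) of mask pixels.
#' @param provenance short label describing what the mask annotates.
#' @export
BinaryMask <- function(values, provenance = "") {
  if (!is.matrix(values)) stop("mask values must be a matrix", call. = FALSE)
  m <- matrix(as.logical(values), nrow(values), ncol(values))
  structure(m, provenance = provenance, class = c("BinaryMask", "matrix"))
}

# Accept BinaryMask or plain logical matrix everywhere.
mask_values <- function(mask) {
  m <- unclass(mask)
  attr(m, "provenance") <- NULL
  if (!is.logical(m)) m <- matrix(as.logical(m), nrow(m), ncol(m))
  m
}

#' Read a grayscale TIFF into an ImageStack
#'
#' Reads a single- or multi-page grayscale TIFF and normalises the axes to
#' `(frame, channel, row, col)`. Pages are assumed channel-interleaved: page
#' `i` holds frame `(i - 1) %/% C + 1`, channel `(i - 1) %% C + 1`. Integer
#' TIFFs are read at their native integer scale (no rescaling to [0, 1]).
#'
#' @param path path to the TIFF file.
#' @param pixel_size_nm,frame_interval_s calibration, supplied by the caller;
#'   arguments always override any file metadata.
#' @param channel_names channel labels; their number sets the channel count
#'   used to de-interleave pages.
#' @return an [ImageStack].
#' @export
read_image_stack <- function(path, pixel_size_nm, frame_interval_s = 0,
                             channel_names = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("unsupported format: RGB or multi-sample TIFF planes", call. = FALSE)
  }
  nc <- length(channel_names)
  np <- length(pages)
  if (np %% nc != 0) {
    stop(sprintf("page count %d is not a multiple of %d channels", np, nc),
         call. = FALSE)
  }
  nf <- np %/% nc
  d <- dim(pages[[1]])
  data <- array(0, c(nf, nc, d[1], d[2]))
  for (i in seq_len(np)) {
    f <- (i - 1L) %/% nc + 1L
    ch <- (i - 1L) %% nc + 1L
    data[f, ch, , ] <- pages[[i]]
  }
  ImageStack(data, pixel_size_nm, frame_interval_s, channel_names)
}

#' Write an ImageStack as a multi-page 16-bit grayscale TIFF
#'
#' Pages are written frame-major with channels interleaved, the layout
#' [read_image_stack()] expects, so integer-valued stacks round-trip exactly.
#' Intensities must be integers in [0, 65535].
#'
#' @param stack an [ImageStack].
#' @param path output path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  x <- stack$data
  if (any(x != round(x)) || max(x) > 65535) {
    stop("16-bit TIFF output requires integer intensities in [0, 65535]",
         call. = FALSE)
  }
  pages <- vector("list", dim(x)[1] * dim(x)[2])
  i <- 1L
  for (f in seq_len(dim(x)[1])) {
    for (ch in seq_len(dim(x)[2])) {
      pages[[i]] <- x[f, ch, , ] / 65535
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as a single-page TIFF
#' @param mask a [BinaryMask] or logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask_values(mask) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path TIFF path.
#' @param provenance label attached to the returned mask.
#' @export
read_mask <- function(path, provenance = "") {
  m <- tiff::readTIFF(path, as.is = TRUE)
  BinaryMask(m > 0, provenance)
}
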
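#' Image stack container
#'
#' A time-ordered set of 2D intensity frames with physical calibration.
#' Frames are stored per channel as a numeric array of dimension
#' `c(ny, nx, n_frames)`; rows are y, columns are x. Pixel indices are
#' 0-based in the package's coordinate convention: a localization
#' `(x_um, y_um)` falls in pixel `(floor(x/ps), floor(y/ps))` whose center
#' is at `(i + 0.5) * ps`.
#'
#' @param channels named list of numeric arrays `c(ny, nx, n_frames)`
#'   (a single matrix is promoted to one frame).
#' @param pixel_size_um pixel size in micrometers (> 0).
#' @param frame_interval_s frame interval in seconds (> 0 for time series;
#'   `NA` allowed for single-timepoint images).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um, frame_interval_s = NA_real_) {
  if (is.matrix(channels) || (is.array(channels) && length(dim(channels)) == 3)) {
    channels <- list(ch1 = channels)
  }
  if (!is.list(channels) || length(channels) == 0) {
    stop_param("channels must be a non-empty (named) list of arrays")
  }
  if (is.null(names(channels)) || any(names(channels) == "")) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (!is.array(ch) || length(dim(ch)) != 3) {
      stop_param("each channel must be a matrix or ny x nx x T array")
    }
    storage.mode(ch) <- "double"
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1) {
    stop_param("all channels must share the same frame shape")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop_param("pixel_size_um must be a positive scalar")
  }
  if (!is.na(frame_interval_s) && frame_interval_s <= 0) {
    stop_param("frame_interval_s must be positive (or NA for single timepoints)")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d px, %d frame(s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.4g um/px, frame interval %s s\n",
              x$pixel_size_um,
              if (is.na(x$frame_interval_s)) "NA" else format(x$frame_interval_s)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$channels[[1]])[3]

get_frame <- function(stack, frame, channel = 1L) {
  stack$channels[[channel]][, , frame]
}

#' Write an image stack to multi-page TIFF
#'
#' Frames of all channels are written channel-major (all frames of channel 1,
#' then channel 2, ...). Calibration and channel layout travel in a YAML
#' sidecar `<path>.yaml`, since baseline TIFF writing here carries no
#' physical metadata. Integer-valued data up to 65535 are stored as 16-bit
#' (lossless); anything else as scaled 32-bit float.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  allv <- unlist(lapply(stack$channels, as.vector), use.names = FALSE)
  integerish <- all(allv >= 0) && all(allv <= 65535) && all(allv == round(allv))
  pages <- list()
  for (ch in stack$channels) {
    for (t in seq_len(dim(ch)[3])) pages[[length(pages) + 1L]] <- ch[, , t]
  }
  if (integerish) {
    mode <- "uint16"; scale <- 1
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    mode <- "float32"
    scale <- max(abs(allv), 1e-300)
    pages <- lapply(pages, function(p) p / scale)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  }
  meta <- list(
    pixel_size_um = stack$pixel_size_um,
    frame_interval_s = if (is.na(stack$frame_interval_s)) NULL else stack$frame_interval_s,
    channels = as.list(names(stack$channels)),
    n_frames = n_frames(stack),
    storage = mode,
    scale = scale
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' Reads a TIFF written by [write_stack()] (using its YAML sidecar), or any
#' plain multi-page TIFF, in which case calibration must be supplied through
#' the override arguments and all pages are treated as one channel unless
#' `channel_map` says otherwise.
#'
#' @param path TIFF path.
#' @param channel_map optional named list `channel name -> page indices`.
#' @param pixel_size_um,frame_interval_s overrides for missing metadata.
#' @return an [image_stack].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       frame_interval_s = NULL) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  # as.is recovers raw integers for integer TIFFs but corrupts float
  # samples, so the storage mode decides how pages are read
  use_as_is <- !identical(meta$storage, "float32")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = use_as_is),
    error = function(e) stop_param("not a readable TIFF ('%s'): %s", path, conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # grayscale stored with extra plane
    p
  })
  if (length(unique(lapply(pages, dim))) != 1) stop_param("non-uniform frame shapes in %s", path)

  if (identical(meta$storage, "uint16")) {
    pages <- lapply(pages, function(p) p * 1.0)
  } else if (identical(meta$storage, "float32")) {
    pages <- lapply(pages, function(p) p * meta$scale)
  }
  ps <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(ps)) stop_param("no pixel size in metadata and no override given for %s", path)
  fi <- frame_interval_s %||% meta$frame_interval_s %||% NA_real_

  ch_names <- channel_map %||% meta$channels
  if (is.null(ch_names)) {
    channels <- list(ch1 = simplify2array(pages))
  } else if (is.list(ch_names) && !is.null(names(ch_names)) && all(nzchar(names(ch_names)))) {
    channels <- lapply(ch_names, function(idx) simplify2array(pages[unlist(idx)]))
  } else {
    # names only: split pages evenly across channels, channel-major
    ch_names <- unlist(ch_names)
    k <- length(ch_names)
    if (length(pages) %% k != 0) stop_param("page count %d not divisible by %d channels",
                                            length(pages), k)
    per <- length(pages) / k
    channels <- stats::setNames(lapply(seq_len(k), function(i) {
      simplify2array(pages[((i - 1) * per + 1):(i * per)])
    }), ch_names)
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) array(ch, dim = c(dim(ch), 1L)) else ch
  })
  image_stack(channels, pixel_size_um = ps, frame_interval_s = fi)
}

#' Subtract a sequence-wide background level
#'
#' One scalar -- the mean intensity over all time points within a background
#' region of interest -- is subtracted from every frame of every channel;
#' negative values are clamped to zero.
#'
#' @param stack an [image_stack].
#' @param roi background region as `list(x, y, width, height)` in 0-based
#'   pixel coordinates, or a logical matrix of the frame shape.
#' @param channel channel used to compute the background mean (default 1).
#' @return the adjusted [image_stack]; the subtracted scalar is attached as
#'   attribute `"background"`.
#' @export
adjust_background <- function(stack, roi, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  if (is.list(roi)) {
    x0 <- roi$x; y0 <- roi$y; w <- roi$width; h <- roi$height
    if (any(vapply(list(x0, y0, w, h), is.null, TRUE))) {
      stop_param("roi needs x, y, width, height")
    }
    if (w <= 0 || h <= 0) stop_param("roi is empty")
    if (x0 < 0 || y0 < 0 || x0 + w > d[2] || y0 + h > d[1]) {
      stop_param("roi outside image bounds")
    }
    sel_rows <- (y0 + 1):(y0 + h)
    sel_cols <- (x0 + 1):(x0 + w)
    roi_mask <- matrix(FALSE, d[1], d[2])
    roi_mask[sel_rows, sel_cols] <- TRUE
  } else {
    roi_mask <- roi > 0
    if (!all(dim(roi_mask) == d[1:2])) stop_param("roi mask shape mismatch")
    if (!any(roi_mask)) stop_param("roi is empty")
  }
  ch <- stack$channels[[channel]]
  bg <- mean(apply(ch, 3, function(fr) mean(fr[roi_mask])))
  out <- stack
  out$channels <- lapply(stack$channels, function(c3) {
    c3 <- c3 - bg
    c3[c3 < 0] <- 0
    c3
  })
  attr(out, "background") <- bg
  out
}
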
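#' Spot detection parameters
#'
#' Parameters of the spot-enhancing filter: a Laplacian-of-Gaussian filter
#' followed by thresholding at `mean(|response|) + threshold_factor * sd(response)`
#' and local-maxima extraction. The threshold factor is held constant across
#' all frames of a sequence.
#'
#' @param log_sigma_px LoG kernel scale in pixels (> 0); match to the spot
#'   radius (PSF sigma) for maximal response.
#' @param threshold_factor factor `c` multiplying the response standard
#'   deviation (>= 0).
#' @param min_separation_px minimal separation between accepted peaks (>= 1).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(log_sigma_px = 1.5, threshold_factor = 3,
                             min_separation_px = 3) {
  if (log_sigma_px <= 0) stop_param("log_sigma_px must be > 0")
  if (threshold_factor < 0) stop_param("threshold_factor must be >= 0")
  if (min_separation_px < 1) stop_param("min_separation_px must be >= 1")
  structure(list(log_sigma_px = log_sigma_px, threshold_factor = threshold_factor,
                 min_separation_px = min_separation_px),
            class = "detection_params")
}

# Sign-corrected LoG kernel: positive response for bright blobs of scale
# sigma. Zero-sum so constant backgrounds map to zero response.
log_kernel <- function(sigma) {
  w <- ceiling(3 * sigma)
  x <- (-w):w
  r2 <- outer(x^2, x^2, "+")
  k <- (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))  # -LoG up to scale
  k - mean(k)
}

#' Detect sub-resolution spots with the spot-enhancing filter
#'
#' LoG-filters the frame (sign-corrected so bright spots give positive
#' peaks), thresholds at `T = mean(|response|) + c * sd(response)`, extracts
#' local maxima strictly above `T` at least `min_separation_px` apart, and
#' refines each to sub-pixel precision by the intensity-weighted centroid of
#' the positive response in a `(2*ceil(2*sigma)+1)^2` window. Positions are
#' returned in micrometers (pixel-center convention).
#'
#' @param frame 2D numeric matrix.
#' @param params a [detection_params].
#' @param pixel_size_um pixel size used for the um conversion.
#' @param mask optional logical nucleus mask (same shape); detections outside
#'   are discarded.
#' @param frame_index frame index recorded in the output (0-based).
#' @return data frame of spots: `frame, x_um, y_um, peak_response,
#'   raw_intensity` (possibly 0 rows).
#' @export
sef_detect <- function(frame, params = detection_params(), pixel_size_um = 1,
                       mask = NULL, frame_index = 0L) {
  frame <- as_frame(frame)
  if (!is.matrix(frame) || length(frame) == 0) stop_param("frame must be a non-empty matrix")
  if (!is.null(mask) && !all(dim(mask) == dim(frame))) {
    stop_param("mask shape does not match frame")
  }
  empty <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      peak_response = numeric(0), raw_intensity = numeric(0))
  if (stats::sd(as.vector(frame)) == 0) return(empty)

  k <- log_kernel(params$log_sigma_px)
  resp <- EBImage::filter2(frame, k, boundary = "replicate")
  resp <- matrix(resp, nrow(frame), ncol(frame))
  thr <- mean(abs(resp)) + params$threshold_factor * stats::sd(as.vector(resp))

  ny <- nrow(resp); nx <- ncol(resp)
  # 8-neighborhood local maxima above threshold (image border excluded);
  # >= admits 2-pixel plateaus (spot centered on a pixel boundary), which
  # the separation suppression below reduces to a single peak
  inner <- resp[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > thr &
    inner >= resp[1:(ny - 2), 2:(nx - 1)] & inner >= resp[3:ny, 2:(nx - 1)] &
    inner >= resp[2:(ny - 1), 1:(nx - 2)] & inner >= resp[2:(ny - 1), 3:nx] &
    inner >= resp[1:(ny - 2), 1:(nx - 2)] & inner >= resp[1:(ny - 2), 3:nx] &
    inner >= resp[3:ny, 1:(nx - 2)] & inner >= resp[3:ny, 3:nx]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  peaks <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                      resp = inner[idx])
  # enforce minimal separation greedily by descending response
  # (deterministic: ties broken by row, then column)
  peaks <- peaks[order(-peaks$resp, peaks$row, peaks$col), ]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      d <- sqrt((peaks$row[j] - peaks$row[i])^2 + (peaks$col[j] - peaks$col[i])^2)
      keep[j][d < params$min_separation_px] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  # sub-pixel refinement: weighted centroid of positive response
  w <- ceiling(2 * params$log_sigma_px)
  rad <- ceiling(2 * params$log_sigma_px)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks$row[i]; cc <- peaks$col[i]
    r0 <- max(1, r - w); r1 <- min(ny, r + w)
    c0 <- max(1, cc - w); c1 <- min(nx, cc + w)
    win <- resp[r0:r1, c0:c1]
    win[win < 0] <- 0
    tot <- sum(win)
    cy <- if (tot > 0) sum(win * (r0:r1)) / tot else r
    cx <- if (tot > 0) sum(t(win) * (c0:c1)) / tot else cc
    # integrated raw intensity in a fixed-radius disk around the peak
    rr0 <- max(1, r - rad); rr1 <- min(ny, r + rad)
    cc0 <- max(1, cc - rad); cc1 <- min(nx, cc + rad)
    disk <- outer((rr0:rr1) - r, (cc0:cc1) - cc,
                  function(a, b) a^2 + b^2) <= rad^2
    raw <- sum(frame[rr0:rr1, cc0:cc1][disk])
    c(row = cy, col = cx, resp = peaks$resp[i], raw = raw)
  })
  out <- do.call(rbind, out)
  if (!is.null(mask)) {
    ri <- pmin(pmax(round(out[, "row"]), 1), ny)
    ci <- pmin(pmax(round(out[, "col"]), 1), nx)
    out <- out[mask[cbind(ri, ci)], , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty)
  res <- data.frame(frame = as.integer(frame_index),
                    x_um = px_to_um(out[, "col"], pixel_size_um),
                    y_um = px_to_um(out[, "row"], pixel_size_um),
                    peak_response = out[, "resp"],
                    raw_intensity = out[, "raw"])
  res[order(res$x_um, res$y_um), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack an [image_stack].
#' @param params a [detection_params]; the same threshold factor is used for
#'   all frames of the sequence.
#' @param channel channel name or index.
#' @param mask optional nucleus mask applied to every frame.
#' @return data frame of spots over all frames (0-based `frame`).
#' @export
detect_stack <- function(stack, params = detection_params(), channel = 1L,
                         mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack$channels[[channel]]
  res <- lapply(seq_len(dim(ch)[3]), function(t) {
    sef_detect(ch[, , t], params, pixel_size_um = stack$pixel_size_um,
               mask = mask, frame_index = t - 1L)
  })
  do.call(rbind, res)
}

#' Segment nuclei by intensity threshold
#'
#' Threshold (manual value or Otsu default), hole filling, one
#' dilation+erosion (morphological closing) pass, connected-component
#' labeling, and a minimal-area filter.
#'
#' @param image 2D numeric matrix (e.g. a DAPI frame).
#' @param min_area_um2 minimal object area in um^2 (default 50).
#' @param pixel_size_um pixel size.
#' @param threshold intensity threshold; `NULL` for Otsu on the rescaled
#'   image.
#' @param brush_size diameter of the disc brush used for closing (px).
#' @return list of nucleus masks, each `list(mask, label, area_um2)`;
#'   empty list if nothing survives.
#' @export
segment_nucleus <- function(image, min_area_um2 = 50, pixel_size_um = 1,
                            threshold = NULL, brush_size = 5) {
  image <- as_frame(image)
  if (!is.matrix(image) || length(image) == 0) stop_param("image must be a non-empty matrix")
  if (is.null(threshold)) {
    rng <- range(image)
    if (diff(rng) == 0) return(list())
    norm <- (image - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  bin <- EBImage::Image((image > threshold) * 1)
  bin <- EBImage::fillHull(bin)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  bin <- EBImage::erode(EBImage::dilate(bin, brush), brush)
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  labm <- matrix(as.numeric(EBImage::imageData(lab)), nrow(image), ncol(image))
  out <- list()
  for (l in seq_len(max(labm))) {
    m <- labm == l
    area <- sum(m) * pixel_size_um^2
    if (area < min_area_um2) next
    out[[length(out) + 1L]] <- list(mask = m, label = length(out) + 1L,
                                    area_um2 = area)
  }
  out
}
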
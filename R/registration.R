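#' Affine drift correction of a time series
#'
#' Aligns every frame to frame 1 of the stack. Translation is estimated by
#' phase correlation (FFT cross-power spectrum, integer peak plus parabolic
#' sub-pixel interpolation). With `mode = "affine"`, the translation is
#' refined to a full affine transform by least squares on matched spot
#' detections (nearest-neighbor matches after translation).
#'
#' The affine-refined transform absorbs any motion common to all particles;
#' with few mobile particles that includes part of their diffusion, so the
#' default for drift correction of sparse live-cell scenes is translation
#' only.
#'
#' @param stack an [image_stack] (>= 2 frames).
#' @param channel channel to register (all channels are warped).
#' @param mode `"translation"` (default) or `"affine"`.
#' @param detect_params [detection_params] for the refinement matching.
#' @return list: `stack` (warped copy), `transforms` (list of 2x3 matrices
#'   `[A | b]`, mapping frame-t pixel coordinates to frame-1 coordinates;
#'   positions `p_1 = A %*% p_t + b` in 0-based pixel units).
#' @export
register_affine <- function(stack, channel = 1L,
                            mode = c("translation", "affine"),
                            detect_params = detection_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack$channels[[channel]]
  nt <- dim(ch)[3]
  if (nt < 2) stop_param("need at least 2 frames to register")
  ref <- ch[, , 1]
  if (stats::sd(as.vector(ref)) == 0) stop_param("reference frame is blank; cannot register")

  # Frame-to-frame estimation, then composition to frame 1. Consecutive
  # frames differ by one step of drift plus one step of particle motion,
  # so nearest-neighbor matching stays unambiguous; matching every frame
  # directly to frame 1 fails once accumulated particle motion exceeds
  # any safe match gate.
  prev_frame <- ref
  prev_spots <- sef_detect(ref, detect_params, pixel_size_um = 1)
  transforms <- vector("list", nt)
  transforms[[1]] <- cbind(diag(2), c(0, 0))
  for (t in 2:nt) {
    fr <- ch[, , t]
    if (stats::sd(as.vector(fr)) == 0) stop_param("frame %d is blank; cannot register", t)
    sh <- phase_correlation(prev_frame, fr)  # shift aligning frame t to t-1
    A <- diag(2); b <- sh
    spots_t <- sef_detect(fr, detect_params, pixel_size_um = 1)
    if (nrow(spots_t) >= 3 && nrow(prev_spots) >= 3) {
      pt <- cbind(spots_t$x_um, spots_t$y_um)  # pixel units (pixel_size 1)
      pr <- cbind(prev_spots$x_um, prev_spots$y_um)
      moved <- sweep(pt, 2, sh, "+")
      nn <- nearest_neighbors(moved, pr)
      keep <- nn$dist < 1.5
      if (sum(keep) >= 3) {
        src <- pt[keep, , drop = FALSE]
        dst <- pr[nn$index[keep], , drop = FALSE]
        if (mode == "affine") {
          X <- cbind(src, 1)
          beta <- tryCatch(qr.solve(X, dst), error = function(e) NULL)
          if (!is.null(beta)) {
            A <- t(beta[1:2, ])
            b <- as.numeric(beta[3, ])
          }
        } else {
          # translation-restricted least squares on the inlier matches
          b <- colMeans(dst - src)
        }
      }
    }
    # compose: p_1 = C_{t-1}( A p_t + b )
    Cp <- transforms[[t - 1]]
    transforms[[t]] <- cbind(Cp[, 1:2] %*% A,
                             as.numeric(Cp[, 1:2] %*% b + Cp[, 3]))
    prev_frame <- fr
    prev_spots <- spots_t
  }

  out <- stack
  out$channels <- lapply(stack$channels, function(c3) {
    res <- c3
    for (t in 2:min(dim(c3)[3], nt)) {
      res[, , t] <- warp_affine(c3[, , t], transforms[[t]])
    }
    res
  })
  list(stack = out, transforms = transforms)
}

# Phase correlation: returns (dx, dy) such that moving `fr` by (dx, dy)
# aligns it with `ref` (i.e. fr(x - dx, y - dy) ~ ref... sign convention:
# ref(x) ~ fr(x - dx) ⇒ applying +(dx,dy) to fr's coordinates maps onto ref).
phase_correlation <- function(ref, fr) {
  Fa <- stats::fft(ref - mean(ref))
  Fb <- stats::fft(fr - mean(fr))
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  # soft whitening: a relative epsilon keeps near-zero spectral magnitudes
  # (smooth, noise-free content) from amplifying numerical noise
  r <- Re(stats::fft(R / (mag + 1e-3 * max(mag)), inverse = TRUE))
  ny <- nrow(r); nx <- ncol(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  # parabolic sub-pixel interpolation around the peak (wrapped neighbors)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den == 0) 0 else 0.5 * (vm - vp) / den
  }
  vy <- c(r[wrap(pk[1] - 1, ny), pk[2]], r[pk[1], pk[2]], r[wrap(pk[1] + 1, ny), pk[2]])
  vx <- c(r[pk[1], wrap(pk[2] - 1, nx)], r[pk[1], pk[2]], r[pk[1], wrap(pk[2] + 1, nx)])
  dy <- pk[1] - 1 + sub(vy[1], vy[2], vy[3])
  dx <- pk[2] - 1 + sub(vx[1], vx[2], vx[3])
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dx, dy)
}

# Inverse-mapping bilinear warp: output(p) = input(Ainv (p - b)) with the
# 2x3 transform mapping input coords to output coords (0-based pixel units,
# x = column index, y = row index).
warp_affine <- function(img, Tr) {
  A <- Tr[, 1:2]; b <- Tr[, 3]
  Ai <- solve(A)
  ny <- nrow(img); nx <- ncol(img)
  gx <- rep(0:(nx - 1), each = ny)
  gy <- rep(0:(ny - 1), times = nx)
  sx <- Ai[1, 1] * (gx - b[1]) + Ai[1, 2] * (gy - b[2])
  sy <- Ai[2, 1] * (gx - b[1]) + Ai[2, 2] * (gy - b[2])
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(xx, yy) {
    ok <- xx >= 0 & xx <= nx - 1 & yy >= 0 & yy <= ny - 1
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, ny, nx)
}

#' Apply estimated transforms to trajectory coordinates
#'
#' Maps each trajectory point through the transform of its frame, so tracks
#' computed on an unregistered stack can be expressed in the reference
#' frame.
#'
#' @param trajs list of [trajectory] objects.
#' @param transforms list of 2x3 matrices from [register_affine()]
#'   (pixel units).
#' @param pixel_size_um pixel size of the stack the transforms refer to.
#' @return list of corrected trajectories.
#' @export
apply_transforms <- function(trajs, transforms, pixel_size_um) {
  lapply(trajs, function(tr) {
    p <- tr$points
    for (k in seq_len(nrow(p))) {
      Tr <- transforms[[p$frame[k] + 1L]]
      xy_px <- c(p$x_um[k], p$y_um[k]) / pixel_size_um
      new <- Tr[, 1:2] %*% xy_px + Tr[, 3]
      p$x_um[k] <- new[1] * pixel_size_um
      p$y_um[k] <- new[2] * pixel_size_um
    }
    trajectory(tr$id, p$frame, p$t_s, p$x_um, p$y_um)
  })
}
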
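# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# All user-facing generators funnel through this so no function touches
# global RNG state as a side effect.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed; kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483629)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Coordinate convention (used everywhere):
## pixel indices are 0-based; pixel i covers [i, i+1) * pixel_size in um and
## its center sits at (i + 0.5) * pixel_size. In R matrices, row r / col c
## (1-based) correspond to 0-based indices (r-1, c-1); x runs along columns,
## y along rows.
um_to_px <- function(u_um, pixel_size_um) u_um / pixel_size_um - 0.5 + 1  # 1-based fractional index
px_to_um <- function(idx1, pixel_size_um) (idx1 - 0.5) * pixel_size_um    # center of 1-based pixel

# Accept a matrix or a single-frame ny x nx x 1 array as a 2D frame.
as_frame <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] != 1) stop_param("expected a single 2D frame, got %d frames", dim(x)[3])
    x <- x[, , 1]
  }
  x
}

# Crofton perimeter estimate from boundary crossings along 4 directions
# (rows, columns and both diagonals). Calibrated so a discrete disk of
# radius r gives ~2*pi*r.
crofton_perimeter <- function(mask) {
  m <- (mask > 0) * 1L
  c0 <- sum(m[, 1]) + sum(m[, ncol(m)]) + sum(abs(m[, -1] - m[, -ncol(m)]))
  c90 <- sum(m[1, ]) + sum(m[nrow(m), ]) + sum(abs(m[-1, ] - m[-nrow(m), ]))
  diag_crossings <- function(m) {
    # crossings along 45-degree lines (constant row+col)
    nr <- nrow(m); nc <- ncol(m)
    tot <- 0L
    for (s in 2:(nr + nc)) {
      r <- max(1L, s - nc):min(nr, s - 1L)
      v <- m[cbind(r, s - r)]
      tot <- tot + sum(abs(diff(v))) + v[1] + v[length(v)]
    }
    tot
  }
  c45 <- diag_crossings(m)
  c135 <- diag_crossings(m[nrow(m):1, , drop = FALSE])
  pi / 8 * (c0 + c90 + (c45 + c135) / sqrt(2))
}

# Population standard deviation (divisor N); pinned convention for cV.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Stable hash of an R object for run manifests (md5 of its serialized JSON).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
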
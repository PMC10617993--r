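# Shared fixtures and independent oracles, built in code at test time.

# Brute-force time-averaged MSD: explicit double loop over start times.
brute_msd <- function(traj, max_lag_s = Inf) {
  p <- traj$points
  n <- nrow(p)
  dt <- p$t_s[2] - p$t_s[1]
  max_k <- min(n - 1, floor(max_lag_s / dt))
  vapply(1:max_k, function(k) {
    acc <- 0
    for (i in 1:(n - k)) {
      acc <- acc + (p$x_um[i + k] - p$x_um[i])^2 + (p$y_um[i + k] - p$y_um[i])^2
    }
    acc / (n - k)
  }, 0)
}

# Brute-force nearest neighbor (same Euclidean arithmetic as the k-d tree).
brute_nn <- function(query_xy, ref_xy) {
  t(apply(query_xy, 1, function(q) {
    d <- sqrt((ref_xy[, 1] - q[1])^2 + (ref_xy[, 2] - q[2])^2)
    c(which.min(d), min(d))
  }))
}

# All permutations of 1..n (for exhaustive assignment checks, n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1), function(p) c(i, (seq_len(n))[-i][p]))
  }))
}

brute_assignment_cost <- function(cost) {
  min(vapply(all_perms(nrow(cost)),
             function(p) sum(cost[cbind(seq_len(nrow(cost)), p)]), 0))
}

# Render a single frame with Gaussian spots at given um positions.
render_frame <- function(xy_um, ny = 64, nx = 64, pixel_size_um = 0.1,
                         psf_sigma_um = 0.13, amplitude = 200, background = 0) {
  sc <- list(pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um)
  chromdyn:::render_spots(matrix(background, ny, nx), xy_um[, 1], xy_um[, 2],
                          sc, amplitudes = rep(amplitude, nrow(xy_um)))
}

# Filled disk mask.
disk_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny) - cy, seq_len(nx) - cx, function(a, b) a^2 + b^2) <= r^2
}

# Match detections/tracks to ground truth positions (greedy NN within tol).
match_points <- function(est_xy, true_xy, tol) {
  used <- rep(FALSE, nrow(true_xy))
  matches <- 0L
  err2 <- numeric(0)
  for (i in seq_len(nrow(est_xy))) {
    d <- sqrt((true_xy[, 1] - est_xy[i, 1])^2 + (true_xy[, 2] - est_xy[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      matches <- matches + 1L
      err2 <- c(err2, d[j]^2)
    }
  }
  list(n_matched = matches, rmse = if (length(err2)) sqrt(mean(err2)) else NA_real_)
}
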
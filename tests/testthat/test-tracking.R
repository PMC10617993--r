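test_that("optimal assignment matches brute-force enumeration", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n)
    sol <- chromdyn:::solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]), brute_assignment_cost(cost),
                 tolerance = 1e-12)
  }
})

test_that("static well-separated spots give zero-displacement trajectories", {
  pts <- rbind(c(1, 1), c(3, 1), c(2, 3))
  spots <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, x_um = pts[, 1], y_um = pts[, 2])
  }))
  trs <- link_spots(spots, tracker_params(), frame_interval_s = 0.5)
  expect_equal(length(trs), 3)
  for (tr in trs) {
    expect_equal(nrow(tr$points), 10)
    expect_equal(diff(tr$points$x_um), rep(0, 9))
    expect_equal(diff(tr$points$y_um), rep(0, 9))
  }
})

test_that("crossing constant-velocity spots keep their identities", {
  # two particles on straight lines crossing mid-sequence, distinct velocities
  n <- 21; dt <- 0.5
  t <- 0:(n - 1)
  ax <- 1 + 0.08 * t; ay <- 2 + 0.04 * t     # moves right+down
  bx <- 2.6 - 0.08 * t; by <- 2 + 0.04 * t   # moves left+down, crosses a
  spots <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(frame = i - 1, x_um = c(ax[i], bx[i]), y_um = c(ay[i], by[i]))
  }))
  trs <- link_spots(spots, tracker_params(gate_radius_um = 0.3),
                    frame_interval_s = dt)
  expect_equal(length(trs), 2)
  # each recovered track follows one generating line throughout
  for (tr in trs) {
    expect_equal(nrow(tr$points), n)
    d_a <- max(abs(tr$points$x_um - ax))
    d_b <- max(abs(tr$points$x_um - bx))
    expect_lt(min(d_a, d_b), 1e-9)  # no identity swap at the crossing
  }
})

test_that("per-frame links agree with an exhaustive assignment oracle", {
  # <= 3 Brownian particles; replay the linking frame by frame and compare
  # each step's matching to brute-force minimal total distance
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    trs <- simulate_trajectories(motion_spec("brownian", D = 1e-3), k, 15, 0.5,
                                 seed = 300 + rep,
                                 origins = cbind(runif(k, 1, 4), runif(k, 1, 4)))
    spots <- do.call(rbind, lapply(trs, function(tr) {
      data.frame(frame = tr$points$frame, x_um = tr$points$x_um,
                 y_um = tr$points$y_um, id = tr$id)
    }))
    linked <- link_spots(spots[, 1:3], tracker_params(), frame_interval_s = 0.5)
    expect_equal(length(linked), k)
    # ground-truth correspondence: each linked track must reproduce exactly
    # one simulated particle's positions (the optimal assignment at every
    # frame, since particles stay well separated relative to their steps)
    for (tr in linked) {
      errs <- vapply(trs, function(gt) {
        max(abs(gt$points$x_um - tr$points$x_um) +
              abs(gt$points$y_um - tr$points$y_um))
      }, 0)
      expect_lt(min(errs), 1e-9)
    }
  }
})

test_that("a track spanning frames 0-14 at 0.5 s lasts 7 s and fails the 10 s filter", {
  spots <- data.frame(frame = 0:14, x_um = 1, y_um = 1)
  trs <- link_spots(spots, frame_interval_s = 0.5)
  expect_equal(length(trs), 1)
  expect_equal(trs[[1]]$duration_s, 7)
  expect_equal(length(filter_trajectories(trs, 10)), 0)
})

test_that("no detection or track is used twice within a frame", {
  set.seed(31)
  spots <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, x_um = runif(5, 0, 3), y_um = runif(5, 0, 3))
  }))
  trs <- link_spots(spots, tracker_params(gate_radius_um = 1), frame_interval_s = 0.5)
  used <- do.call(rbind, lapply(seq_along(trs), function(i) {
    cbind(id = i, trs[[i]]$points[, c("frame", "x_um", "y_um")])
  }))
  for (f in unique(used$frame)) {
    sub <- used[used$frame == f, ]
    expect_false(any(duplicated(sub[, c("x_um", "y_um")])))   # one det per track
    expect_false(any(duplicated(sub$id)))                     # one det per track id
  }
})

test_that("within-frame detection order does not change the trajectories", {
  set.seed(41)
  spots <- do.call(rbind, lapply(0:7, function(f) {
    data.frame(frame = f, x_um = runif(4, 0, 3) , y_um = runif(4, 0, 3))
  }))
  shuffled <- do.call(rbind, lapply(split(spots, spots$frame),
                                    function(g) g[sample(nrow(g)), ]))
  a <- link_spots(spots, frame_interval_s = 0.5)
  b <- link_spots(shuffled, frame_interval_s = 0.5)
  key <- function(trs) {
    sort(vapply(trs, function(tr) {
      paste(sprintf("%.9f", c(tr$points$x_um, tr$points$y_um)), collapse = ",")
    }, ""))
  }
  expect_identical(key(a), key(b))
})

test_that("identity transform is recovered on an untranslated stack", {
  sc <- scene_spec(n_particles = 6, n_frames = 4, seed = 51, noise = "none")
  st <- render_movie(simulate_scene(sc, motion_spec("static")))
  reg <- register_affine(st)
  for (Tr in reg$transforms) {
    expect_lt(max(abs(Tr - cbind(diag(2), c(0, 0)))), 0.02)
  }
})

test_that("a known translation is recovered within 0.1 px", {
  sc <- scene_spec(n_particles = 8, n_frames = 4, seed = 52, noise = "none")
  st <- render_movie(simulate_scene(sc, motion_spec("static")))
  arr <- st$channels$chromatin
  for (t in 2:4) {
    arr[, , t] <- chromdyn:::warp_affine(arr[, , 1], cbind(diag(2), c(3.2, -1.7)))
  }
  st$channels$chromatin <- arr
  reg <- register_affine(st)
  for (t in 2:4) {
    expect_lt(max(abs(reg$transforms[[t]][, 3] - c(-3.2, 1.7))), 0.1)
  }
})

test_that("a 2-degree rotation is recovered within 0.1 px mean landmark error", {
  sc <- scene_spec(n_particles = 10, n_frames = 3, seed = 53, noise = "none")
  st <- render_movie(simulate_scene(sc, motion_spec("static")))
  th <- 2 * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ctr <- c(64, 64)
  b <- as.numeric(ctr - Rm %*% ctr)
  arr <- st$channels$chromatin
  for (t in 2:3) arr[, , t] <- chromdyn:::warp_affine(arr[, , 1], cbind(Rm, b))
  st$channels$chromatin <- arr
  reg <- register_affine(st, mode = "affine")
  # true frame-t -> frame-1 map is the inverse of (Rm, b)
  inv <- cbind(solve(Rm), as.numeric(-solve(Rm) %*% b))
  set.seed(1)
  pts <- cbind(runif(50, 30, 100), runif(50, 30, 100))
  est <- t(reg$transforms[[2]][, 1:2] %*% t(pts) + reg$transforms[[2]][, 3])
  tru <- t(inv[, 1:2] %*% t(pts) + inv[, 3])
  expect_lt(mean(sqrt(rowSums((est - tru)^2))), 0.1)
})

test_that("blank frames make registration fail loudly", {
  st <- image_stack(list(ch = array(3, c(32, 32, 3))), pixel_size_um = 0.1,
                    frame_interval_s = 0.5)
  expect_error(register_affine(st), "blank")
})
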
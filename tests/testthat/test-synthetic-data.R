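test_that("static motion without noise produces exactly zero displacement", {
  trs <- simulate_trajectories(motion_spec("static"), 3, 10, 0.5, seed = 1)
  for (tr in trs) {
    expect_equal(diff(tr$points$x_um), rep(0, 9))
    expect_equal(diff(tr$points$y_um), rep(0, 9))
  }
})

test_that("Brownian ensemble MSD matches the closed form 4*D*dt at lag 1", {
  D <- 1e-3; dt <- 0.5
  trs <- simulate_trajectories(motion_spec("brownian", D = D), 2000, 41, dt, seed = 42)
  ens <- ensemble_msd(lapply(trs, compute_msd))
  expect_lt(abs(ens$msd_um2[1] / (4 * D * dt) - 1), 0.05)
})

test_that("fBm ensemble MSD has log-log slope alpha over lags 1-10", {
  trs <- simulate_trajectories(motion_spec("fbm_subdiffusive", D = 1e-3, alpha = 0.5),
                               2000, 41, 0.5, seed = 43)
  ens <- ensemble_msd(lapply(trs, compute_msd))
  sel <- 1:10
  slope <- coef(lm(log(ens$msd_um2[sel]) ~ log(ens$lags_s[sel])))[2]
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("ensemble MSD matches 4*D*t^alpha within Monte-Carlo error across alphas", {
  for (alpha in c(0.3, 0.5, 1.0)) {
    D <- 1e-3; dt <- 0.5
    model <- if (alpha == 1) motion_spec("brownian", D = D)
             else motion_spec("fbm_subdiffusive", D = D, alpha = alpha)
    trs <- simulate_trajectories(model, 1500, 21, dt, seed = 100 + round(10 * alpha))
    ens <- ensemble_msd(lapply(trs, compute_msd))
    expected <- 4 * D * ens$lags_s^alpha
    # relative error bounded by 3 SEM (SEM from the across-trajectory spread)
    rel_tol <- pmax(3 * ens$sem_um2 / expected, 0.02)
    expect_true(all(abs(ens$msd_um2 / expected - 1) < rel_tol),
                info = sprintf("alpha = %g", alpha))
  }
})

test_that("generators are bit-reproducible given the same seed", {
  a <- simulate_trajectories(motion_spec("brownian", D = 1e-3), 5, 11, 0.5, seed = 7)
  b <- simulate_trajectories(motion_spec("brownian", D = 1e-3), 5, 11, 0.5, seed = 7)
  expect_identical(a, b)
  sc <- scene_spec(n_particles = 4, n_frames = 3, seed = 9)
  s1 <- render_movie(simulate_scene(sc, motion_spec("brownian", D = 1e-3)))
  s2 <- render_movie(simulate_scene(sc, motion_spec("brownian", D = 1e-3)))
  expect_identical(s1$channels$chromatin, s2$channels$chromatin)
})

test_that("confined motion never exceeds the confinement radius", {
  R <- 0.25
  trs <- simulate_trajectories(motion_spec("confined", D = 5e-3, confinement_radius = R),
                               20, 200, 0.5, seed = 12)
  for (tr in trs) {
    r <- sqrt(tr$points$x_um^2 + tr$points$y_um^2)
    expect_true(all(r <= R + 1e-12))
  }
})

test_that("invalid motion parameters are rejected", {
  expect_error(motion_spec("brownian", D = -1), "D must be")
  expect_error(motion_spec("fbm_subdiffusive", D = 1e-3, alpha = 2.5), "alpha")
  expect_error(motion_spec("confined", D = 1e-3), "confinement_radius")
  expect_error(motion_spec("static", loc_noise_sd = -0.1), "loc_noise_sd")
})

test_that("rendered frame peaks at the pixel containing the true position", {
  sc <- scene_spec(n_particles = 1, n_frames = 2, noise = "none", background = 0)
  tr <- list(trajectory(1, 0:1, c(0, 0.5), rep(2.03, 2), rep(3.17, 2)))
  truth <- structure(list(trajectories = tr, motion = list(motion_spec("static")),
                          scene = sc), class = "ground_truth")
  fr <- render_movie(truth)$channels$chromatin[, , 1]
  pk <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(pk[1, "col"]), floor(2.03 / 0.1) + 1)  # 1-based col
  expect_equal(unname(pk[1, "row"]), floor(3.17 / 0.1) + 1)
})

test_that("total rendered intensity matches the analytic Gaussian integral", {
  sc <- scene_spec(n_particles = 5, n_frames = 2, noise = "none", background = 7,
                   seed = 21)
  truth <- simulate_scene(sc, motion_spec("static"))
  fr <- render_movie(truth)$channels$chromatin[, , 1]
  sigma_px <- sc$psf_sigma_um / sc$pixel_size_um
  expected <- 5 * sc$amplitude * 2 * pi * sigma_px^2
  observed <- sum(fr) - 7 * length(fr)
  expect_lt(abs(observed / expected - 1), 0.01)
})

test_that("rendering errors out when a particle leaves the field of view", {
  sc <- scene_spec(n_particles = 1, n_frames = 2, noise = "none")
  tr <- list(trajectory(1, 0:1, c(0, 0.5), c(2, 50), c(2, 2)))  # exits in frame 2
  truth <- structure(list(trajectories = tr, motion = list(motion_spec("static")),
                          scene = sc), class = "ground_truth")
  expect_error(render_movie(truth), "field of view")
})

test_that("proximity scenes realize their distance plan exactly (brute force)", {
  plan <- c(0, 0.3, 1.5, 0.8)
  px <- make_proximity_scene(4, 6, plan, seed = 5)
  starts <- t(vapply(px$truth$trajectories,
                     function(tr) c(tr$points$x_um[1], tr$points$y_um[1]),
                     numeric(2)))
  bf <- brute_nn(starts, px$pcna_um)
  expect_equal(bf[, 2], plan, tolerance = 1e-9)
  # zero-distance focus coincides with a PCNA focus
  expect_lt(bf[1, 2], 1e-12)
  # CCD truth labels at R = 0.5 um
  expect_identical(bf[, 2] <= 0.5, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("population truth tables hit the requested S fraction and totals", {
  rec <- make_population_records(500, 0.4, seed = 31)
  phat <- mean(rec$is_sphase)
  expect_lt(abs(phat - 0.4), 1.96 * sqrt(0.4 * 0.6 / 500) + 1e-9)
  # rendered population: per-nucleus protein totals match the truth table
  pop <- make_population_image(5, 0.4, seed = 32, img_size_px = c(384, 384))
  seg <- segment_nuclei_watershed(pop$stack$channels$dapi,
                                  intensity_threshold = 200,
                                  min_area_um2 = 30, pixel_size_um = 0.3)
  wp <- wavelet_foci(pop$stack$channels$protein, seg$labels, level = 1)
  for (i in seq_len(nrow(seg$records))) {
    d <- sqrt((pop$truth$cx_um - seg$records$cx_um[i])^2 +
                (pop$truth$cy_um - seg$records$cy_um[i])^2)
    j <- which.min(d)
    expect_lt(abs(wp$per_nucleus$total_nuclear_intensity[i] /
                    pop$truth$protein_total_intensity[j] - 1), 0.01)
  }
})

test_that("sphase_fraction = 0 leaves every nucleus below the EdU gate", {
  rec <- make_population_records(200, 0, foci_count_law = list(s_mean = 80, non_s_mean = 15),
                                 seed = 33)
  gated <- gate_sphase(rec, gate_spec(), "control")
  expect_false(any(gated$is_sphase_gated))
})

test_that("trajectory CSV round-trips", {
  trs <- simulate_trajectories(motion_spec("brownian", D = 1e-3), 3, 6, 0.5, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trajectories(trs, f)
  back <- read_trajectories(f)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$points$x_um, trs[[2]]$points$x_um)
})
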
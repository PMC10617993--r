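#' Motion model specification
#'
#' Describes the stochastic motion of a simulated chromatin focus.
#' The ensemble mean squared displacement of the generated 2D motion is
#' `4 * D * t^alpha` (plus the localization-noise offset `4 * loc_noise_sd^2`
#' when noise is present).
#'
#' @param model one of `"brownian"`, `"fbm_subdiffusive"`, `"confined"`,
#'   `"static"`.
#' @param D diffusion coefficient in um^2/s (>= 0).
#' @param alpha anomalous exponent in (0, 2]; used by `fbm_subdiffusive`.
#' @param confinement_radius reflecting-boundary radius in um
#'   (`confined` only).
#' @param loc_noise_sd localization noise s.d. in um, added independently
#'   per coordinate per frame.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(model = c("brownian", "fbm_subdiffusive", "confined", "static"),
                        D = 0, alpha = 1, confinement_radius = NULL,
                        loc_noise_sd = 0) {
  model <- match.arg(model)
  if (!is.numeric(D) || D < 0) stop_param("D must be >= 0")
  if (model == "fbm_subdiffusive" && (alpha <= 0 || alpha > 2)) {
    stop_param("alpha must be in (0, 2] for fbm_subdiffusive")
  }
  if (model == "confined") {
    if (is.null(confinement_radius) || confinement_radius <= 0) {
      stop_param("confinement_radius must be > 0 for confined motion")
    }
  }
  if (loc_noise_sd < 0) stop_param("loc_noise_sd must be >= 0")
  structure(list(model = model, D = D, alpha = alpha,
                 confinement_radius = confinement_radius,
                 loc_noise_sd = loc_noise_sd),
            class = "motion_spec")
}

#' Trajectory constructor
#'
#' @param id trajectory identifier.
#' @param frame integer frame indices (0-based, strictly increasing).
#' @param t_s time in seconds.
#' @param x_um,y_um positions in micrometers.
#' @return object of class `trajectory` with a `points` data frame and
#'   `duration_s = (n_points - 1) * frame interval`.
#' @export
trajectory <- function(id, frame, t_s, x_um, y_um) {
  if (is.unsorted(frame, strictly = TRUE)) stop_param("frames must be strictly increasing")
  pts <- data.frame(frame = as.integer(frame), t_s = t_s, x_um = x_um, y_um = y_um)
  structure(list(id = id, points = pts,
                 duration_s = if (nrow(pts) > 1) pts$t_s[nrow(pts)] - pts$t_s[1] else 0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> %d points, frames %d-%d, duration %.3g s\n",
              format(x$id), nrow(x$points), x$points$frame[1],
              x$points$frame[nrow(x$points)], x$duration_s))
  invisible(x)
}

# Cholesky factor of the fractional-Gaussian-noise increment covariance,
# for unit-variance fBm with Hurst H sampled at interval dt.
fgn_chol <- function(n_steps, H, dt) {
  k <- outer(seq_len(n_steps), seq_len(n_steps), function(i, j) abs(i - j))
  gamma <- dt^(2 * H) / 2 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  chol(gamma)
}

#' Simulate ground-truth trajectories
#'
#' Generates `n` 2D trajectories of `n_frames` points at interval `dt`
#' following a [motion_spec]:
#' * `brownian` -- i.i.d. Gaussian increments with per-axis variance
#'   `2*D*dt` (ensemble MSD `4*D*t`);
#' * `fbm_subdiffusive` -- per-axis fractional Brownian motion with
#'   `H = alpha/2`, scaled so the ensemble MSD is `4*D*t^alpha`;
#' * `confined` -- Brownian steps with reflection at
#'   `confinement_radius` around the start point;
#' * `static` -- constant position.
#' Localization noise (`loc_noise_sd`) is added per coordinate per frame
#' for every model.
#'
#' @param motion a [motion_spec].
#' @param n number of trajectories (>= 1).
#' @param n_frames points per trajectory (>= 2).
#' @param dt frame interval in seconds (> 0).
#' @param seed RNG seed.
#' @param origins optional `n x 2` matrix of start positions in um
#'   (default: all at the origin).
#' @return list of [trajectory] objects (true positions, in um).
#' @export
simulate_trajectories <- function(motion, n, n_frames, dt, seed,
                                  origins = NULL) {
  stopifnot(inherits(motion, "motion_spec"))
  if (n < 1) stop_param("n must be >= 1")
  if (n_frames < 2) stop_param("n_frames must be >= 2")
  if (dt <= 0) stop_param("dt must be > 0")
  if (is.null(origins)) origins <- matrix(0, n, 2)
  origins <- matrix(origins, ncol = 2)
  if (nrow(origins) != n) stop_param("origins must have n rows")

  n_steps <- n_frames - 1L
  t_s <- (0:n_steps) * dt
  with_seed(seed, {
    paths <- switch(motion$model,
      static = replicate(n, matrix(0, n_frames, 2), simplify = FALSE),
      brownian = {
        sdd <- sqrt(2 * motion$D * dt)
        replicate(n, {
          steps <- matrix(stats::rnorm(n_steps * 2, sd = sdd), n_steps, 2)
          rbind(c(0, 0), apply(steps, 2, cumsum))
        }, simplify = FALSE)
      },
      fbm_subdiffusive = {
        H <- motion$alpha / 2
        L <- fgn_chol(n_steps, H, dt)   # gamma = t(L) %*% L
        amp <- sqrt(2 * motion$D)       # per-axis Var = 2 D t^alpha
        replicate(n, {
          incr <- amp * (t(L) %*% matrix(stats::rnorm(n_steps * 2), n_steps, 2))
          rbind(c(0, 0), apply(incr, 2, cumsum))
        }, simplify = FALSE)
      },
      confined = {
        sdd <- sqrt(2 * motion$D * dt)
        R <- motion$confinement_radius
        replicate(n, {
          p <- matrix(0, n_frames, 2)
          for (i in 2:n_frames) {
            cand <- p[i - 1, ] + stats::rnorm(2, sd = sdd)
            r <- sqrt(sum(cand^2))
            if (r > R) cand <- cand * (2 * R - r) / r  # radial reflection
            p[i, ] <- cand
          }
          p
        }, simplify = FALSE)
      }
    )
    lapply(seq_len(n), function(i) {
      p <- paths[[i]]
      p[, 1] <- p[, 1] + origins[i, 1]
      p[, 2] <- p[, 2] + origins[i, 2]
      if (motion$loc_noise_sd > 0) {
        p <- p + matrix(stats::rnorm(length(p), sd = motion$loc_noise_sd),
                        nrow(p), 2)
      }
      trajectory(i, 0:n_steps, t_s, p[, 1], p[, 2])
    })
  })
}

#' Scene specification for rendered movies
#'
#' Geometry, optics and noise of a simulated acquisition: particles inside
#' an elliptical nucleus, imaged as Gaussian spots on a pixel grid.
#'
#' @param n_particles particle count.
#' @param n_frames frames (>= 2); default 41 emulating a 20 s series at
#'   0.5 s per frame.
#' @param frame_interval_s frame interval (s).
#' @param pixel_size_um pixel size (um/px).
#' @param img_size_px `c(ny, nx)` image size in pixels.
#' @param nucleus ellipse `list(cx_um, cy_um, ax_um, ay_um)` (center and
#'   semi-axes); default centered, filling most of the field.
#' @param psf_sigma_um Gaussian spot s.d. (um).
#' @param amplitude peak intensity of one in-focus spot (counts).
#' @param background mean background level (counts).
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sd s.d. for Gaussian noise.
#' @param min_separation_um minimal distance between particle start
#'   positions.
#' @param seed RNG seed used for placement and rendering noise.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(n_particles = 10, n_frames = 41, frame_interval_s = 0.5,
                       pixel_size_um = 0.1, img_size_px = c(128, 128),
                       nucleus = NULL, psf_sigma_um = 0.13,
                       amplitude = 500, background = 20,
                       noise = c("poisson", "gaussian", "none"),
                       noise_sd = 3, min_separation_um = 1.2, seed = 1L) {
  noise <- match.arg(noise)
  if (n_frames < 2) stop_param("n_frames must be >= 2")
  if (pixel_size_um <= 0 || psf_sigma_um <= 0) stop_param("pixel and PSF sizes must be > 0")
  fov <- img_size_px * pixel_size_um  # (y, x) extent in um
  if (is.null(nucleus)) {
    nucleus <- list(cx_um = fov[2] / 2, cy_um = fov[1] / 2,
                    ax_um = 0.42 * fov[2], ay_um = 0.35 * fov[1])
  }
  structure(list(n_particles = n_particles, n_frames = n_frames,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, img_size_px = img_size_px,
                 nucleus = nucleus, psf_sigma_um = psf_sigma_um,
                 amplitude = amplitude, background = background,
                 noise = noise, noise_sd = noise_sd,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

inside_ellipse <- function(x, y, nuc, margin_um = 0) {
  ((x - nuc$cx_um) / (nuc$ax_um - margin_um))^2 +
    ((y - nuc$cy_um) / (nuc$ay_um - margin_um))^2 <= 1
}

# Rejection-sample k points inside the nucleus ellipse with pairwise
# minimal separation.
place_in_nucleus <- function(k, scene, min_sep = scene$min_separation_um,
                             margin_um = 0.5) {
  nuc <- scene$nucleus
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pts) < k) {
    tries <- tries + 1
    if (tries > 20000) stop_param("cannot place %d particles without overlap; nucleus too crowded", k)
    x <- nuc$cx_um + stats::runif(1, -1, 1) * (nuc$ax_um - margin_um)
    y <- nuc$cy_um + stats::runif(1, -1, 1) * (nuc$ay_um - margin_um)
    if (!inside_ellipse(x, y, nuc, margin_um)) next
    if (nrow(pts) > 0 && min(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2)) < min_sep) next
    pts <- rbind(pts, c(x, y))
  }
  pts
}

#' Simulate a full ground-truthed scene
#'
#' Places particles inside the nucleus and simulates their motion.
#'
#' @param scene a [scene_spec].
#' @param motion a [motion_spec], or a list of one per particle.
#' @return object of class `ground_truth`: `trajectories`, `motion`,
#'   `scene`.
#' @export
simulate_scene <- function(scene, motion) {
  stopifnot(inherits(scene, "scene_spec"))
  specs <- if (inherits(motion, "motion_spec")) {
    rep(list(motion), scene$n_particles)
  } else motion
  if (length(specs) != scene$n_particles) stop_param("need one motion spec per particle")
  origins <- with_seed(derive_seed(scene$seed, 1), place_in_nucleus(scene$n_particles, scene))
  trajs <- vector("list", scene$n_particles)
  for (i in seq_len(scene$n_particles)) {
    tr <- simulate_trajectories(specs[[i]], 1, scene$n_frames,
                                scene$frame_interval_s,
                                seed = derive_seed(scene$seed, 100 + i),
                                origins = origins[i, , drop = FALSE])[[1]]
    tr$id <- i
    trajs[[i]] <- tr
  }
  structure(list(trajectories = trajs, motion = specs, scene = scene),
            class = "ground_truth")
}

# Add Gaussian spots to a frame; positions in um, frame modified in place.
render_spots <- function(frame, xs_um, ys_um, scene, amplitudes = NULL) {
  ps <- scene$pixel_size_um
  s_px <- scene$psf_sigma_um / ps
  w <- ceiling(6 * s_px)
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(amplitudes)) amplitudes <- rep(scene$amplitude, length(xs_um))
  for (i in seq_along(xs_um)) {
    cx <- xs_um[i] / ps + 0.5  # 1-based fractional pixel index
    cy <- ys_um[i] / ps + 0.5
    c0 <- max(1L, floor(cx) - w); c1 <- min(nx, floor(cx) + w)
    r0 <- max(1L, floor(cy) - w); r1 <- min(ny, floor(cy) + w)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-((c0:c1) - cx)^2 / (2 * s_px^2))
    gy <- exp(-((r0:r1) - cy)^2 / (2 * s_px^2))
    frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + amplitudes[i] * outer(gy, gx)
  }
  frame
}

#' Render a ground-truth scene as a movie
#'
#' Each frame is the sum of isotropic Gaussian spots at the true particle
#' positions, plus background, plus noise per the scene spec. Deterministic
#' given the scene seed.
#'
#' @param truth a `ground_truth` from [simulate_scene()].
#' @return an [image_stack] with one channel `"chromatin"`.
#' @export
render_movie <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  scene <- truth$scene
  ny <- scene$img_size_px[1]; nx <- scene$img_size_px[2]
  fov <- c(nx, ny) * scene$pixel_size_um
  for (tr in truth$trajectories) {
    if (any(tr$points$x_um < 0 | tr$points$x_um > fov[1] |
            tr$points$y_um < 0 | tr$points$y_um > fov[2])) {
      stop_param("particle leaves the field of view; enlarge the image or shrink the nucleus")
    }
  }
  arr <- array(0, dim = c(ny, nx, scene$n_frames))
  for (t in seq_len(scene$n_frames)) {
    fr <- matrix(scene$background, ny, nx)
    xs <- vapply(truth$trajectories, function(tr) tr$points$x_um[t], 0)
    ys <- vapply(truth$trajectories, function(tr) tr$points$y_um[t], 0)
    arr[, , t] <- render_spots(fr, xs, ys, scene)
  }
  arr <- with_seed(derive_seed(scene$seed, 2), {
    if (scene$noise == "poisson") {
      array(stats::rpois(length(arr), lambda = arr), dim = dim(arr))
    } else if (scene$noise == "gaussian") {
      arr + array(stats::rnorm(length(arr), sd = scene$noise_sd), dim = dim(arr))
    } else arr
  })
  image_stack(list(chromatin = arr), pixel_size_um = scene$pixel_size_um,
              frame_interval_s = scene$frame_interval_s)
}

#' Two-channel chromatin + PCNA proximity scene
#'
#' Places `n_pcna` replication (PCNA) foci in the nucleus, then places each
#' chromatin focus at its planned center-to-center distance from its nearest
#' PCNA focus. The PCNA channel is a single reference frame; the chromatin
#' channel is a time series whose particles move per `motion`.
#'
#' @param n_chromatin,n_pcna focus counts.
#' @param distance_plan numeric vector (length `n_chromatin`) of planned
#'   nearest-neighbor distances in um.
#' @param seed RNG seed.
#' @param scene a [scene_spec] (its `n_particles` is ignored).
#' @param motion a [motion_spec] or list of one per chromatin focus
#'   (default: static, no noise).
#' @return list with `stack` (two-channel [image_stack]; PCNA frame
#'   replicated to the series length for storage), `truth`
#'   (`ground_truth` for the chromatin particles), `pcna_um` (matrix of
#'   PCNA centers), `distance_plan`.
#' @export
make_proximity_scene <- function(n_chromatin, n_pcna, distance_plan, seed,
                                 scene = scene_spec(), motion = NULL) {
  if (length(distance_plan) != n_chromatin) {
    stop_param("distance_plan must have one entry per chromatin focus")
  }
  if (is.null(motion)) motion <- motion_spec("static")
  specs <- if (inherits(motion, "motion_spec")) rep(list(motion), n_chromatin) else motion
  scene$n_particles <- n_chromatin
  scene$seed <- as.integer(seed)
  nuc <- scene$nucleus
  placed <- with_seed(derive_seed(seed, 11), {
    pcna <- place_in_nucleus(n_pcna, scene, min_sep = max(distance_plan) + 0.5)
    chrom <- matrix(NA_real_, n_chromatin, 2)
    for (i in seq_len(n_chromatin)) {
      d <- distance_plan[i]
      ok <- FALSE
      for (try in 1:5000) {
        j <- sample.int(n_pcna, 1)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- pcna[j, ] + d * c(cos(th), sin(th))
        if (!inside_ellipse(cand[1], cand[2], nuc, 0.5)) next
        dists <- sqrt(rowSums((pcna - matrix(cand, n_pcna, 2, byrow = TRUE))^2))
        if (abs(min(dists) - d) > 1e-9) next  # planned partner must be the nearest
        if (i > 1 && any(sqrt(rowSums((chrom[seq_len(i - 1), , drop = FALSE] -
                matrix(cand, i - 1, 2, byrow = TRUE))^2)) < 0.3)) next
        chrom[i, ] <- cand
        ok <- TRUE
        break
      }
      if (!ok) stop_param("distance plan infeasible within the nucleus (focus %d, d = %g um)", i, d)
    }
    list(pcna = pcna, chrom = chrom)
  })
  trajs <- vector("list", n_chromatin)
  for (i in seq_len(n_chromatin)) {
    tr <- simulate_trajectories(specs[[i]], 1, scene$n_frames,
                                scene$frame_interval_s,
                                seed = derive_seed(seed, 200 + i),
                                origins = placed$chrom[i, , drop = FALSE])[[1]]
    tr$id <- i
    trajs[[i]] <- tr
  }
  truth <- structure(list(trajectories = trajs, motion = specs, scene = scene),
                     class = "ground_truth")
  chrom_stack <- render_movie(truth)
  pcna_frame <- render_spots(matrix(scene$background,
                                    scene$img_size_px[1], scene$img_size_px[2]),
                             placed$pcna[, 1], placed$pcna[, 2], scene)
  pcna_frame <- with_seed(derive_seed(seed, 12), {
    if (scene$noise == "poisson") {
      matrix(stats::rpois(length(pcna_frame), pcna_frame), nrow(pcna_frame))
    } else if (scene$noise == "gaussian") {
      pcna_frame + matrix(stats::rnorm(length(pcna_frame), sd = scene$noise_sd),
                          nrow(pcna_frame))
    } else pcna_frame
  })
  stack <- image_stack(
    list(chromatin = chrom_stack$channels$chromatin,
         pcna = array(pcna_frame, dim = c(dim(pcna_frame), 1L))),
    pixel_size_um = scene$pixel_size_um,
    frame_interval_s = scene$frame_interval_s
  )
  list(stack = stack, truth = truth, pcna_um = placed$pcna,
       distance_plan = distance_plan)
}

#' Per-nucleus truth records for a synthetic cell population
#'
#' Fast, render-free generator of the per-nucleus measurements the
#' high-content stage consumes: EdU focus counts drawn from Poisson laws
#' whose means differ between S-phase and non-S-phase cells, and protein
#' focal totals drawn from a Gaussian law (optionally shifted, emulating a
#' treatment effect).
#'
#' @param n_nuclei nuclei count.
#' @param sphase_fraction true S-phase fraction in `[0, 1]`.
#' @param foci_count_law `list(s_mean, non_s_mean)` Poisson means of EdU
#'   focus counts for S and non-S nuclei.
#' @param protein_intensity_law `list(mean, sd, shift)`; `shift` (default 0)
#'   is added to the mean, in units of `sd`.
#' @param seed RNG seed.
#' @return data frame: `label, is_sphase, edu_foci_count,
#'   protein_total_intensity, mean_edu_intensity`.
#' @export
make_population_records <- function(n_nuclei, sphase_fraction,
                                    foci_count_law = list(s_mean = 80, non_s_mean = 15),
                                    protein_intensity_law = list(mean = 1000, sd = 200, shift = 0),
                                    seed = 1L) {
  if (sphase_fraction < 0 || sphase_fraction > 1) stop_param("sphase_fraction must be in [0,1]")
  with_seed(seed, {
    s <- stats::runif(n_nuclei) < sphase_fraction
    edu <- ifelse(s, stats::rpois(n_nuclei, foci_count_law$s_mean),
                  stats::rpois(n_nuclei, foci_count_law$non_s_mean))
    shift <- protein_intensity_law$shift %||% 0
    prot <- stats::rnorm(n_nuclei,
                         mean = protein_intensity_law$mean + shift * protein_intensity_law$sd,
                         sd = protein_intensity_law$sd)
    data.frame(label = seq_len(n_nuclei), is_sphase = s,
               edu_foci_count = as.integer(edu),
               protein_total_intensity = prot,
               mean_edu_intensity = 5 + 2 * edu / max(1, mean(edu)))
  })
}

#' Render a synthetic multi-channel cell-population image
#'
#' DAPI channel with non-overlapping disk nuclei; EdU channel with
#' per-nucleus focus counts drawn above (S-phase) or below (non-S) the
#' gating threshold; protein channel with controlled per-nucleus focal
#' totals. Returns the image and the truth table.
#'
#' @inheritParams make_population_records
#' @param img_size_px image size `c(ny, nx)`.
#' @param pixel_size_um pixel size.
#' @param nucleus_radius_um nucleus disk radius.
#' @param seed RNG seed.
#' @return list: `stack` ([image_stack], channels `dapi`, `edu`,
#'   `protein`), `truth` data frame (`label, cx_um, cy_um, radius_um,
#'   is_sphase, edu_foci_count, protein_total_intensity`).
#' @export
make_population_image <- function(n_nuclei, sphase_fraction,
                                  foci_count_law = list(s_mean = 80, non_s_mean = 15),
                                  protein_intensity_law = list(mean = 20000, sd = 4000, shift = 0),
                                  seed = 1L, img_size_px = c(512, 512),
                                  pixel_size_um = 0.3, nucleus_radius_um = 8,
                                  focus_separation_um = 1.05) {
  if (sphase_fraction < 0 || sphase_fraction > 1) stop_param("sphase_fraction must be in [0,1]")
  ny <- img_size_px[1]; nx <- img_size_px[2]
  fov <- c(nx, ny) * pixel_size_um
  r <- nucleus_radius_um
  with_seed(seed, {
    # non-overlapping nucleus centers
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centers) < n_nuclei) {
      tries <- tries + 1
      if (tries > 50000) stop_param("cannot place %d nuclei without overlap", n_nuclei)
      cand <- c(stats::runif(1, r + 1, fov[1] - r - 1),
                stats::runif(1, r + 1, fov[2] - r - 1))
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2, byrow = TRUE))^2))) < 2.2 * r) next
      centers <- rbind(centers, cand)
    }
    s <- stats::runif(n_nuclei) < sphase_fraction
    edu_n <- ifelse(s, stats::rpois(n_nuclei, foci_count_law$s_mean),
                    stats::rpois(n_nuclei, foci_count_law$non_s_mean))
    shift <- protein_intensity_law$shift %||% 0
    prot_tot <- stats::rnorm(n_nuclei,
                             protein_intensity_law$mean + shift * protein_intensity_law$sd,
                             protein_intensity_law$sd)
    prot_tot <- pmax(prot_tot, 0.1 * protein_intensity_law$mean)

    xs <- seq(0.5, nx - 0.5) * pixel_size_um
    ysv <- seq(0.5, ny - 0.5) * pixel_size_um
    dapi <- matrix(0, ny, nx)
    for (i in seq_len(n_nuclei)) {
      dx2 <- (xs - centers[i, 1])^2
      dy2 <- (ysv - centers[i, 2])^2
      d2 <- outer(dy2, dx2, "+")
      dapi <- dapi + 800 / (1 + exp((sqrt(d2) - r) / 0.2))  # soft-edged disk
    }
    spot_scene <- list(pixel_size_um = pixel_size_um, psf_sigma_um = 0.25,
                       amplitude = 1, background = 0)
    sigma_int <- 2 * pi * (spot_scene$psf_sigma_um / pixel_size_um)^2  # integral of unit-amp spot
    # rejection-sample k focus positions in a disk with pairwise separation
    place_in_disk <- function(k, cx, cy, rad, min_sep) {
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(pts) < k) {
        tries <- tries + 1
        if (tries > 40000) stop_param("cannot place %d foci with %.2f um separation in a %.1f um nucleus",
                                      k, min_sep, rad)
        th <- stats::runif(1, 0, 2 * pi)
        rr <- (rad - 1) * sqrt(stats::runif(1))
        cand <- c(cx + rr * cos(th), cy + rr * sin(th))
        if (nrow(pts) > 0 &&
            min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) < min_sep) next
        pts <- rbind(pts, cand)
      }
      pts
    }
    edu <- matrix(0, ny, nx)
    protein <- matrix(0, ny, nx)
    for (i in seq_len(n_nuclei)) {
      k <- edu_n[i]
      if (k > 0) {
        p <- place_in_disk(k, centers[i, 1], centers[i, 2], r, focus_separation_um)
        edu <- render_spots(edu, p[, 1], p[, 2], spot_scene,
                            amplitudes = rep(200, k))
      }
      kp <- 25L
      pp <- place_in_disk(kp, centers[i, 1], centers[i, 2], r, focus_separation_um)
      amp_each <- prot_tot[i] / (kp * sigma_int)
      protein <- render_spots(protein, pp[, 1], pp[, 2], spot_scene,
                              amplitudes = rep(amp_each, kp))
    }
    truth <- data.frame(label = seq_len(n_nuclei),
                        cx_um = centers[, 1], cy_um = centers[, 2],
                        radius_um = r, is_sphase = s,
                        edu_foci_count = as.integer(edu_n),
                        protein_total_intensity = prot_tot)
    stack <- image_stack(list(dapi = dapi, edu = edu, protein = protein),
                         pixel_size_um = pixel_size_um)
    list(stack = stack, truth = truth)
  })
}

#' Write ground-truth trajectories as CSV
#'
#' Columns: `particle_id, frame, t_s, x_um, y_um`.
#'
#' @param trajs list of [trajectory] objects (or a `ground_truth`).
#' @param path output CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "ground_truth")) trajs <- trajs$trajectories
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    cbind(particle_id = tr$id, tr$points)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV (inverse of [write_trajectories()])
#' @param path CSV path with columns `particle_id/track_id, frame, t_s, x_um, y_um`.
#' @return list of [trajectory] objects.
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path)
  idcol <- if ("particle_id" %in% names(d)) "particle_id" else "track_id"
  lapply(split(d, d[[idcol]]), function(g) {
    g <- g[order(g$frame), ]
    trajectory(g[[idcol]][1], g$frame, g$t_s, g$x_um, g$y_um)
  })
}
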
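#' Tracker parameters
#'
#' Configuration of the probabilistic linker: a constant-velocity Kalman
#' filter per live track predicts the next position; predictions and
#' detections are matched by minimum-total-cost assignment within a gate,
#' where the cost is the Mahalanobis distance under the innovation
#' covariance plus a penalty proportional to the disagreement with the mean
#' of the last `motion_memory` displacements.
#'
#' @param gate_radius_um maximal prediction-to-detection distance (um);
#'   default 0.5 um, several times the expected per-step displacement of
#'   chromatin foci at 0.5 s frame intervals.
#' @param process_noise Kalman process-noise variance (um^2 per step).
#' @param measurement_noise Kalman measurement-noise variance (um^2).
#' @param max_missed_frames frames a track may coast unmatched before
#'   termination; default 0 (no gap closing).
#' @param motion_memory number of past displacements averaged in the
#'   motion-consistency penalty.
#' @param memory_weight weight of that penalty (cost units per um).
#' @return object of class `tracker_params`.
#' @export
tracker_params <- function(gate_radius_um = 0.5, process_noise = 4e-3,
                           measurement_noise = 4e-4, max_missed_frames = 0L,
                           motion_memory = 3L, memory_weight = 2) {
  if (gate_radius_um <= 0) stop_param("gate_radius_um must be > 0")
  if (max_missed_frames < 0) stop_param("max_missed_frames must be >= 0")
  structure(list(gate_radius_um = gate_radius_um, process_noise = process_noise,
                 measurement_noise = measurement_noise,
                 max_missed_frames = as.integer(max_missed_frames),
                 motion_memory = as.integer(motion_memory),
                 memory_weight = memory_weight),
            class = "tracker_params")
}

new_kalman <- function(x, y, q, r) {
  list(state = c(x, y, 0, 0),
       P = diag(c(r, r, 10 * q, 10 * q)),
       q = q, r = r)
}

kalman_predict <- function(kf) {
  F_ <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
  Q <- diag(c(kf$q / 4, kf$q / 4, kf$q, kf$q))
  kf$state <- as.numeric(F_ %*% kf$state)
  kf$P <- F_ %*% kf$P %*% t(F_) + Q
  kf
}

kalman_update <- function(kf, z) {
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  S <- H %*% kf$P %*% t(H) + diag(kf$r, 2)
  K <- kf$P %*% t(H) %*% solve(S)
  innov <- z - as.numeric(H %*% kf$state)
  kf$state <- as.numeric(kf$state + K %*% innov)
  kf$P <- (diag(4) - K %*% H) %*% kf$P
  kf
}

innovation_cov <- function(kf) {
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  H %*% kf$P %*% t(H) + diag(kf$r, 2)
}

#' Link per-frame detections into trajectories
#'
#' Detections (as produced by [detect_stack()]) are linked frame by frame.
#' Within each frame, detections are put in a canonical order (by x, then
#' y) before assignment, so the result does not depend on their input
#' order. Unmatched detections start new tracks; tracks unmatched for more
#' than `max_missed_frames` frames terminate. All trajectories are
#' returned; duration filtering is a downstream analysis step
#' (see [filter_trajectories()]).
#'
#' @param spots data frame with columns `frame, x_um, y_um` (0-based frame
#'   indices), or a list of per-frame data frames.
#' @param params a [tracker_params].
#' @param frame_interval_s frame interval used to timestamp points.
#' @return list of [trajectory] objects.
#' @export
link_spots <- function(spots, params = tracker_params(), frame_interval_s = 0.5) {
  if (is.list(spots) && !is.data.frame(spots)) {
    spots <- do.call(rbind, lapply(seq_along(spots), function(i) {
      s <- spots[[i]]
      if (nrow(s) > 0) s$frame <- i - 1L
      s
    }))
  }
  if (is.null(spots) || nrow(spots) == 0) return(list())
  if (any(spots$frame < 0) || any(spots$frame != round(spots$frame))) {
    stop_param("frame indices must be non-negative integers")
  }
  frames <- sort(unique(spots$frame))
  all_frames <- seq(min(frames), max(frames))

  tracks <- list()     # active: list(kf, points(matrix frame,x,y), missed, disps)
  finished <- list()
  next_id <- 1L

  for (f in all_frames) {
    det <- spots[spots$frame == f, , drop = FALSE]
    det <- det[order(det$x_um, det$y_um), , drop = FALSE]
    nd <- nrow(det)
    nt <- length(tracks)

    # predict all live tracks
    tracks <- lapply(tracks, function(tr) { tr$kf <- kalman_predict(tr$kf); tr })

    assigned_det <- rep(FALSE, nd)
    if (nt > 0 && nd > 0) {
      gate2 <- params$gate_radius_um^2
      cost <- matrix(Inf, nt, nd)
      for (i in seq_len(nt)) {
        kf <- tracks[[i]]$kf
        pred <- kf$state[1:2]
        Sinv <- solve(innovation_cov(kf))
        mem <- tracks[[i]]$disps
        mean_disp <- if (length(mem) > 0) {
          Reduce(`+`, mem) / length(mem)
        } else c(0, 0)
        last <- tracks[[i]]$last_pos
        for (j in seq_len(nd)) {
          dz <- c(det$x_um[j] - pred[1], det$y_um[j] - pred[2])
          if (sum(dz^2) > gate2) next
          maha <- sqrt(as.numeric(t(dz) %*% Sinv %*% dz))
          step <- c(det$x_um[j], det$y_um[j]) - last
          pen <- params$memory_weight * sqrt(sum((step - mean_disp)^2))
          cost[i, j] <- maha + pen
        }
      }
      # pad so rows/columns can stay unassigned at a bounded cost
      A <- 1e3; M <- 1e9
      cost[cost >= A] <- M
      big_cost <- rbind(cbind(cost, matrix(A, nt, nt)),
                        cbind(matrix(A, nd, nd), matrix(0, nd, nt)))
      sol <- solve_assignment(big_cost)
      for (i in seq_len(nt)) {
        j <- sol[i]
        if (j <= nd && cost[i, j] < A) {
          z <- c(det$x_um[j], det$y_um[j])
          tr <- tracks[[i]]
          tr$kf <- kalman_update(tr$kf, z)
          tr$points <- rbind(tr$points, c(f, z))
          tr$disps <- c(tr$disps, list(z - tr$last_pos))
          if (length(tr$disps) > params$motion_memory) {
            tr$disps <- tr$disps[-1]
          }
          tr$last_pos <- z
          tr$missed <- 0L
          tracks[[i]] <- tr
          assigned_det[j] <- TRUE
        } else {
          tracks[[i]]$missed <- tracks[[i]]$missed + 1L
        }
      }
    } else if (nt > 0) {
      tracks <- lapply(tracks, function(tr) { tr$missed <- tr$missed + 1L; tr })
    }

    # retire tracks that coasted too long
    dead <- vapply(tracks, function(tr) tr$missed > params$max_missed_frames, TRUE)
    finished <- c(finished, tracks[dead])
    tracks <- tracks[!dead]

    # unmatched detections start new tracks
    for (j in which(!assigned_det)) {
      z <- c(det$x_um[j], det$y_um[j])
      tracks[[length(tracks) + 1L]] <- list(
        kf = new_kalman(z[1], z[2], params$process_noise, params$measurement_noise),
        points = matrix(c(f, z), 1, 3), disps = list(),
        last_pos = z, missed = 0L, id = next_id)
      next_id <- next_id + 1L
    }
    if (nt == 0 && nd > 0 && length(tracks) > 0) {
      # first frame with detections: nothing else to do
    }
  }
  finished <- c(finished, tracks)
  finished <- finished[order(vapply(finished, function(tr) tr$id, 1L))]
  lapply(seq_along(finished), function(k) {
    p <- finished[[k]]$points
    trajectory(k, p[, 1], p[, 1] * frame_interval_s, p[, 2], p[, 3])
  })
}
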
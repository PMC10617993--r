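#' Classify trajectories by distance to the nearest replication focus
#'
#' For each eligible chromatin trajectory -- present at the first time
#' point of the sequence and of duration at least `min_duration_s` -- the
#' Euclidean distance from its first-time-point position to the nearest
#' PCNA focus is computed with a k-d tree, and the trajectory is grouped as
#' `within` the center-to-center distance (CCD) if that distance is
#' `<= R_um` (inclusive boundary), else `outside`.
#'
#' @param trajs list of [trajectory] objects.
#' @param pcna_spots data frame with `x_um, y_um` (reference-frame PCNA
#'   detections), or a 2-column matrix.
#' @param R_um CCD threshold in um (> 0).
#' @param min_duration_s eligibility duration (default 10 s).
#' @param first_frame index of the sequence's first frame (default 0).
#' @return data frame: `track_id, nearest_pcna_distance_um, nearest_pcna,
#'   R_um, group`; zero rows if nothing is eligible.
#' @export
classify_ccd <- function(trajs, pcna_spots, R_um, min_duration_s = 10,
                         first_frame = 0L) {
  if (R_um <= 0) stop_param("R_um must be > 0")
  pc <- if (is.data.frame(pcna_spots)) cbind(pcna_spots$x_um, pcna_spots$y_um)
        else as.matrix(pcna_spots)
  if (is.null(pc) || nrow(pc) == 0) stop_param("PCNA spot set is empty")
  eligible <- Filter(function(tr) {
    tr$points$frame[1] == first_frame && tr$duration_s >= min_duration_s
  }, trajs)
  if (length(eligible) == 0) {
    return(data.frame(track_id = integer(0), nearest_pcna_distance_um = numeric(0),
                      nearest_pcna = integer(0), R_um = numeric(0),
                      group = character(0)))
  }
  q <- t(vapply(eligible, function(tr) c(tr$points$x_um[1], tr$points$y_um[1]),
                numeric(2)))
  nn <- nearest_neighbors(q, pc)
  data.frame(
    track_id = vapply(eligible, function(tr) as.integer(tr$id), 1L),
    nearest_pcna_distance_um = nn$dist,
    nearest_pcna = nn$index,
    R_um = R_um,
    group = ifelse(nn$dist <= R_um, "within", "outside")
  )
}

#' Mobility statistics by CCD group over a grid of radii
#'
#' For each radius `R` in `R_grid`, trajectories are grouped within/outside
#' the CCD and each group's ensemble MSD is fitted with the anomalous
#' diffusion model. Cells where a group is empty (or too small to fit) are
#' reported with `NA` estimates rather than failing.
#'
#' @param trajs list of [trajectory] objects.
#' @param pcna_spots as in [classify_ccd()].
#' @param R_grid numeric vector of radii in um.
#' @param min_duration_s eligibility duration.
#' @param max_lag_s,fit_lag_range passed to the motion analysis.
#' @return data frame: `R_um, group, n_trajectories, D, alpha,
#'   motion_class`.
#' @export
msd_by_group <- function(trajs, pcna_spots, R_grid, min_duration_s = 10,
                         max_lag_s = 20, fit_lag_range = NULL) {
  if (length(R_grid) == 0) stop_param("R_grid must be non-empty")
  base <- classify_ccd(trajs, pcna_spots, R_um = max(R_grid),
                       min_duration_s = min_duration_s)
  rows <- list()
  for (R in R_grid) {
    grp <- ifelse(base$nearest_pcna_distance_um <= R, "within", "outside")
    for (g in c("within", "outside")) {
      ids <- base$track_id[grp == g]
      sub <- Filter(function(tr) tr$id %in% ids, trajs)
      if (length(sub) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          R_um = R, group = g, n_trajectories = 0L,
          D = NA_real_, alpha = NA_real_, motion_class = NA_character_)
        next
      }
      res <- tryCatch(
        analyze_motion(sub, min_duration_s = min_duration_s,
                       max_lag_s = max_lag_s, fit_lag_range = fit_lag_range),
        error = function(e) list(n_trajectories = length(sub), fit = NULL))
      fit <- res$fit
      rows[[length(rows) + 1L]] <- data.frame(
        R_um = R, group = g, n_trajectories = res$n_trajectories,
        D = if (is.null(fit)) NA_real_ else fit$D,
        alpha = if (is.null(fit)) NA_real_ else fit$alpha,
        motion_class = if (is.null(fit)) NA_character_ else fit$motion_class)
    }
  }
  do.call(rbind, rows)
}
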
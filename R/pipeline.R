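#' Default mobility-pipeline configuration
#'
#' A single declarative configuration for the end-to-end chromatin
#' mobility analysis on synthetic scenes: one entry per named condition,
#' each with a motion model, plus the scene, detection, tracking and
#' motion-analysis parameter blocks. All defaults are centralized here and
#' recorded in the run manifest.
#'
#' @param conditions named list; each element is a list with `motion`
#'   (a [motion_spec]) and optionally `n_scenes`.
#' @param scene a [scene_spec].
#' @param detection a [detection_params].
#' @param tracker a [tracker_params].
#' @param min_duration_s,max_lag_s,fit_lag_range motion-analysis settings.
#' @param fit_mode `"ensemble"` or `"per_trajectory"`.
#' @param register `FALSE`, `"translation"` or `"affine"`.
#' @param seed run seed.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return a config list.
#' @export
mobility_config <- function(conditions, scene = scene_spec(),
                            detection = detection_params(),
                            tracker = tracker_params(),
                            min_duration_s = 10, max_lag_s = 20,
                            fit_lag_range = NULL,
                            fit_mode = "ensemble", register = FALSE,
                            seed = 1L, out_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) > 0, !is.null(names(conditions)))
  list(conditions = conditions, scene = scene, detection = detection,
       tracker = tracker, min_duration_s = min_duration_s,
       max_lag_s = max_lag_s, fit_lag_range = fit_lag_range,
       fit_mode = fit_mode, register = register,
       seed = as.integer(seed), out_dir = out_dir)
}

#' Run the chromatin-mobility pipeline on synthetic conditions
#'
#' For every condition: simulate ground-truth scenes, render movies,
#' detect spots frame by frame (SEF), link them into trajectories
#' (Kalman + gated optimal assignment), filter by minimal duration,
#' compute ensemble MSD curves and fit the anomalous diffusion model.
#' Deterministic given the config and seed. When `out_dir` is set, writes
#' per-condition `tracks_<cond>.csv`, `msd_<cond>.csv`, a `summary.json`
#' (per-condition trajectory counts, D, alpha) and a `manifest.json`
#' (config hash, seed, package version), plus an MSD figure.
#'
#' @param config from [mobility_config()].
#' @return list: per-condition results (`tracks`, `msd`, `fit`,
#'   `n_trajectories`), `summary` data frame, `manifest`.
#' @export
run_mobility_pipeline <- function(config) {
  t_start <- Sys.time()
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...)))
  }
  results <- list()
  summary_rows <- list()
  for (ci in seq_along(config$conditions)) {
    cname <- names(config$conditions)[ci]
    cond <- config$conditions[[ci]]
    n_scenes <- cond$n_scenes %||% 1L
    all_tracks <- list()
    stage <- "simulate/render"
    res <- tryCatch({
      for (s in seq_len(n_scenes)) {
        scene <- config$scene
        scene$seed <- derive_seed(config$seed, ci * 1000 + s)
        stage <- "simulate"
        truth <- simulate_scene(scene, cond$motion)
        stage <- "render"
        stack <- render_movie(truth)
        if (!isFALSE(config$register)) {
          stage <- "register"
          stack <- register_affine(stack, mode = config$register)$stack
        }
        stage <- "detect"
        spots <- detect_stack(stack, config$detection)
        stage <- "track"
        tracks <- link_spots(spots, config$tracker,
                             frame_interval_s = scene$frame_interval_s)
        for (tr in tracks) {
          tr$id <- sprintf("%s_s%d_t%d", cname, s, tr$id)
          all_tracks[[length(all_tracks) + 1L]] <- tr
        }
      }
      stage <- "motion_analysis"
      analyze_motion(all_tracks, min_duration_s = config$min_duration_s,
                     max_lag_s = config$max_lag_s,
                     fit_lag_range = config$fit_lag_range,
                     fit_mode = config$fit_mode)
    }, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s' (condition '%s'): %s",
                   stage, cname, conditionMessage(e)), call. = FALSE)
    })
    res$tracks <- all_tracks
    results[[cname]] <- res
    log_msg(cname, "%d tracks, %d kept; D = %s, alpha = %s",
            length(all_tracks), res$n_trajectories,
            if (is.null(res$fit)) "NA" else sprintf("%.3g", res$fit$D),
            if (is.null(res$fit)) "NA" else sprintf("%.3f", res$fit$alpha))
    summary_rows[[cname]] <- data.frame(
      condition = cname,
      n_trajectories = res$n_trajectories,
      D_um2_s = if (is.null(res$fit)) NA_real_ else res$fit$D,
      D_um2_s_1e5 = if (is.null(res$fit)) NA_real_ else res$fit$D * 1e5,
      alpha = if (is.null(res$fit)) NA_real_ else res$fit$alpha,
      motion_class = if (is.null(res$fit)) NA_character_ else res$fit$motion_class)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("chromdyn")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cname in names(results)) {
      write_trajectories(results[[cname]]$tracks,
                         file.path(config$out_dir, sprintf("tracks_%s.csv", cname)))
      msd <- results[[cname]]$msd
      if (!is.null(msd)) {
        utils::write.csv(data.frame(lag_s = msd$lags_s, msd_um2 = msd$msd_um2,
                                    sem_um2 = msd$sem_um2, n = msd$n_pairs),
                         file.path(config$out_dir, sprintf("msd_%s.csv", cname)),
                         row.names = FALSE)
      }
    }
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary, manifest = manifest),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(config$out_dir, "msd_curves.png"), 800, 600)
    plot_msd_conditions(results)
    grDevices::dev.off()
  }
  list(results = results, summary = summary, manifest = manifest)
}

plot_msd_conditions <- function(results) {
  cols <- grDevices::hcl.colors(max(3, length(results)), "Dark 2")
  first <- TRUE
  i <- 0
  for (cname in names(results)) {
    i <- i + 1
    msd <- results[[cname]]$msd
    if (is.null(msd)) next
    if (first) {
      plot(msd, log = "xy", add_sem = TRUE, col = cols[i], main = "Ensemble MSD")
      first <- FALSE
    } else {
      graphics::lines(msd$lags_s, msd$msd_um2, type = "b", pch = 16, col = cols[i])
    }
  }
  graphics::legend("topleft", legend = names(results), col = cols[seq_along(results)],
                   pch = 16, bty = "n")
}

#' Run the high-content (HTS) pipeline on control/treated populations
#'
#' Per condition: obtain nucleus records (from a rendered population image
#' via watershed segmentation and wavelet foci counting, or directly from
#' a supplied records table), gate S-phase nuclei by EdU focus count,
#' compute the EdU-positive fraction, and compare S-phase protein
#' accumulation between treated and control with the Wilcoxon rank-sum
#' test.
#'
#' @param config list with elements `control` and `treated` (each either a
#'   records data frame or a list accepted by [make_population_records()]),
#'   `gate` (a [gate_spec]), `edu_background` (default 0), `seed`,
#'   optional `out_dir`.
#' @return list: per-condition gated records, `edu_positive`,
#'   `sphase_fraction`, and `comparison` (`statistic`, `p_value`) on
#'   S-phase protein totals.
#' @export
run_hts_pipeline <- function(config) {
  gate <- config$gate %||% gate_spec()
  get_records <- function(x, cond_name, k) {
    if (is.data.frame(x)) return(x)
    if (is.null(x)) stop(sprintf("pipeline halted at stage 'gating': condition '%s' is empty",
                                 cond_name), call. = FALSE)
    do.call(make_population_records,
            c(x, list(seed = derive_seed(config$seed %||% 1L, k))))
  }
  ctrl <- get_records(config$control, "control", 1)
  trt <- get_records(config$treated, "treated", 2)
  if (nrow(ctrl) == 0) stop("pipeline halted at stage 'gating': condition 'control' is empty",
                            call. = FALSE)
  if (nrow(trt) == 0) stop("pipeline halted at stage 'gating': condition 'treated' is empty",
                           call. = FALSE)
  ctrl <- gate_sphase(ctrl, gate, "control")
  trt <- gate_sphase(trt, gate, "treated")
  bg <- config$edu_background %||% 0
  cmp <- compare_conditions(
    trt$protein_total_intensity[trt$is_sphase_gated],
    ctrl$protein_total_intensity[ctrl$is_sphase_gated])
  out <- list(
    control = ctrl, treated = trt,
    sphase_fraction = c(control = mean(ctrl$is_sphase_gated),
                        treated = mean(trt$is_sphase_gated)),
    edu_positive = c(control = edu_positive_fraction(ctrl, bg),
                     treated = edu_positive_fraction(trt, bg)),
    comparison = cmp,
    manifest = list(seed = config$seed %||% NA,
                    config_hash = config_hash(config[setdiff(names(config), "out_dir")]))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rbind(cbind(condition = "control", ctrl),
                           cbind(condition = "treated", trt)),
                     file.path(config$out_dir, "nuclei.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(sphase_fraction = as.list(out$sphase_fraction),
           edu_positive = as.list(out$edu_positive),
           wilcoxon_p = cmp$p_value, manifest = out$manifest),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(config$out_dir, "protein_boxplot.png"), 600, 600)
    graphics::boxplot(
      list(control = ctrl$protein_total_intensity[ctrl$is_sphase_gated],
           treated = trt$protein_total_intensity[trt$is_sphase_gated]),
      ylab = "total protein focal intensity (a.u.)",
      main = sprintf("S-phase nuclei, Wilcoxon p = %.3g", cmp$p_value))
    grDevices::dev.off()
  }
  out
}
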
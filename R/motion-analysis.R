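#' Time-averaged mean squared displacement of one trajectory
#'
#' For each lag `k*dt <= max_lag_s`, the MSD is the mean over all start
#' times of the squared displacement `|r(t + k*dt) - r(t)|^2`
#' (time-averaged, overlapping windows).
#'
#' @param traj a [trajectory] with uniform frame spacing.
#' @param max_lag_s maximal lag in seconds (default: full span).
#' @return object of class `msd_curve`: `lags_s`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_s = Inf) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$points
  n <- nrow(p)
  if (n < 2) stop_param("trajectory needs at least 2 points")
  steps <- diff(p$frame)
  if (length(unique(steps)) != 1) stop_param("non-uniform sampling; frames must be evenly spaced")
  dt <- (p$t_s[2] - p$t_s[1])
  max_k <- min(n - 1, floor(max_lag_s / dt))
  if (max_k < 1) stop_param("max_lag_s smaller than one frame interval")
  lags <- (1:max_k) * dt
  msd <- numeric(max_k)
  npairs <- integer(max_k)
  x <- p$x_um; y <- p$y_um
  for (k in 1:max_k) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    msd[k] <- mean(dx^2 + dy^2)
    npairs[k] <- n - k
  }
  structure(list(lags_s = lags, msd_um2 = msd, n_pairs = npairs,
                 sem_um2 = rep(NA_real_, max_k)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, dt = %.3g s, MSD(%.3g s) = %.4g um^2\n",
              length(x$lags_s), x$lags_s[1], x$lags_s[1], x$msd_um2[1]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, log = "xy", add_sem = TRUE, ...) {
  graphics::plot(x$lags_s, x$msd_um2, log = log, xlab = expression(Delta * t ~ "(s)"),
                 ylab = expression(MSD ~ (mu * m^2)), type = "b", pch = 16, ...)
  if (add_sem && !all(is.na(x$sem_um2))) {
    graphics::arrows(x$lags_s, x$msd_um2 - x$sem_um2, x$lags_s,
                     x$msd_um2 + x$sem_um2, angle = 90, code = 3,
                     length = 0.02, col = "grey40")
  }
  invisible(x)
}

#' Keep trajectories at least a minimal duration long
#'
#' Retains trajectories of duration `>= min_duration_s`. The default of
#' 10 s corresponds to 20 time steps at 0.5 s per frame; the boundary is
#' inclusive, so a 10 s track is kept.
#'
#' @param trajs list of [trajectory] objects.
#' @param min_duration_s minimal duration in seconds (>= 0).
#' @return filtered list.
#' @export
filter_trajectories <- function(trajs, min_duration_s = 10) {
  if (min_duration_s < 0) stop_param("min_duration_s must be >= 0")
  trajs[vapply(trajs, function(tr) tr$duration_s >= min_duration_s, TRUE)]
}

#' Ensemble-average MSD curves
#'
#' Per-lag unweighted mean across trajectories; the per-lag SEM is the
#' standard deviation across curves divided by the square root of the
#' number of curves contributing to that lag. All curves must share the
#' same lag spacing; curves may end at different maximal lags.
#'
#' @param curves list of [compute_msd()] outputs.
#' @param min_count drop lags where fewer than this many curves contribute.
#' @return an `msd_curve` with `sem_um2` filled in.
#' @export
ensemble_msd <- function(curves, min_count = 2L) {
  if (length(curves) == 0) stop_param("no curves to average")
  dts <- vapply(curves, function(cv) cv$lags_s[1], 0)
  if (max(abs(dts - dts[1])) > 1e-9) stop_param("curves have mismatched lag grids")
  dt <- dts[1]
  max_k <- max(vapply(curves, function(cv) length(cv$lags_s), 1L))
  mat <- matrix(NA_real_, length(curves), max_k)
  for (i in seq_along(curves)) {
    k <- length(curves[[i]]$msd_um2)
    if (max(abs(curves[[i]]$lags_s - (1:k) * dt)) > 1e-9) {
      stop_param("curves have mismatched lag grids")
    }
    mat[i, 1:k] <- curves[[i]]$msd_um2
  }
  counts <- colSums(!is.na(mat))
  keep <- counts >= max(1L, min_count)
  if (length(curves) == 1) keep <- counts >= 1L
  mean_msd <- colMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  sem <- sdv / sqrt(counts)
  structure(list(lags_s = (1:max_k)[keep] * dt, msd_um2 = mean_msd[keep],
                 n_pairs = counts[keep], sem_um2 = sem[keep]),
            class = "msd_curve")
}

#' Fit the anomalous diffusion model to an MSD curve
#'
#' Fits the two-dimensional anomalous diffusion model
#' `MSD(dt) = 4 * D * dt^alpha`. The default fit is a least-squares line in
#' `log(MSD)` versus `log(dt)` over the fit window: `alpha` is the slope
#' and `D = exp(intercept) / 4`. `method = "nls"` refines the log-log
#' estimates by nonlinear least squares on the linear scale.
#'
#' The motion class follows the anomalous-exponent ranges: confined for
#' `alpha <= 0.1`, obstructed for `0.1 < alpha < 0.9`, normal for
#' `0.9 <= alpha <= 1.1`, super for `alpha > 1.1`.
#'
#' @param curve an `msd_curve`.
#' @param fit_lag_range `c(min_s, max_s)` lag window; default from the
#'   first lag up to `min(5 s, 25%` of the maximal lag`)`.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return object of class `diffusion_fit` with elements `D` (um^2/s),
#'   `alpha`, `fit_lags`, `motion_class`, `n_lags`.
#' @export
fit_anomalous <- function(curve, fit_lag_range = NULL,
                          method = c("loglog", "nls")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "msd_curve"))
  if (is.null(fit_lag_range)) {
    fit_lag_range <- c(curve$lags_s[1],
                       max(curve$lags_s[1] * 3,
                           min(5, 0.25 * max(curve$lags_s))))
  }
  sel <- curve$lags_s >= fit_lag_range[1] - 1e-12 &
    curve$lags_s <= fit_lag_range[2] + 1e-12
  lags <- curve$lags_s[sel]
  msd <- curve$msd_um2[sel]
  if (length(lags) < 3) stop_param("need at least 3 lags in the fit range")
  if (any(msd <= 0)) stop_param("non-positive MSD values in the fit range")
  fit <- stats::lm(log(msd) ~ log(lags))
  alpha <- unname(stats::coef(fit)[2])
  D <- unname(exp(stats::coef(fit)[1]) / 4)
  if (method == "nls") {
    nl <- tryCatch(
      suppressWarnings(
        stats::nls(msd ~ 4 * D * lags^a, start = list(D = D, a = alpha),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      D <- unname(cf["D"]); alpha <- unname(cf["a"])
    }
  }
  cls <- motion_class(alpha)
  structure(list(D = D, alpha = alpha, fit_lags = range(lags),
                 motion_class = cls, n_lags = length(lags), method = method),
            class = "diffusion_fit")
}

motion_class <- function(alpha) {
  if (alpha <= 0.1) "confined"
  else if (alpha < 0.9) "obstructed"
  else if (alpha <= 1.1) "normal"
  else "super"
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s (%.1f x 1e-5), alpha = %.3f (%s)\n",
              x$D, x$D * 1e5, x$alpha, x$motion_class))
  cat(sprintf("  fitted over lags %.3g-%.3g s (%d points, %s)\n",
              x$fit_lags[1], x$fit_lags[2], x$n_lags, x$method))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$D, alpha = object$alpha)
}

#' @export
predict.diffusion_fit <- function(object, lags_s, ...) {
  4 * object$D * lags_s^object$alpha
}

#' Per-condition motion analysis
#'
#' The full motion-analysis step on a set of trajectories: duration filter,
#' per-trajectory MSDs, ensemble average and anomalous-diffusion fit.
#' `fit_mode = "ensemble"` (default) fits the ensemble curve;
#' `"per_trajectory"` fits each trajectory and averages the fitted `D` and
#' `alpha`.
#'
#' @param trajs list of [trajectory] objects.
#' @param min_duration_s duration filter (default 10 s).
#' @param max_lag_s maximal MSD lag (default 20 s).
#' @param fit_lag_range passed to [fit_anomalous()].
#' @param fit_mode `"ensemble"` or `"per_trajectory"`.
#' @return list: `n_trajectories`, `msd` (ensemble `msd_curve`), `fit`
#'   (`diffusion_fit`), and for per-trajectory mode `fits` plus the
#'   averaged `D`/`alpha` inside `fit`.
#' @export
analyze_motion <- function(trajs, min_duration_s = 10, max_lag_s = 20,
                           fit_lag_range = NULL,
                           fit_mode = c("ensemble", "per_trajectory")) {
  fit_mode <- match.arg(fit_mode)
  kept <- filter_trajectories(trajs, min_duration_s)
  if (length(kept) == 0) {
    return(list(n_trajectories = 0L, msd = NULL, fit = NULL))
  }
  curves <- lapply(kept, compute_msd, max_lag_s = max_lag_s)
  ens <- ensemble_msd(curves)
  if (fit_mode == "ensemble") {
    fit <- fit_anomalous(ens, fit_lag_range)
    list(n_trajectories = length(kept), msd = ens, fit = fit)
  } else {
    fits <- lapply(curves, function(cv) {
      tryCatch(fit_anomalous(cv, fit_lag_range), error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, TRUE)]
    Dm <- mean(vapply(fits, function(f) f$D, 0))
    am <- mean(vapply(fits, function(f) f$alpha, 0))
    fit <- structure(list(D = Dm, alpha = am,
                          fit_lags = fits[[1]]$fit_lags,
                          motion_class = motion_class(am),
                          n_lags = fits[[1]]$n_lags,
                          method = "per_trajectory_mean"),
                     class = "diffusion_fit")
    list(n_trajectories = length(kept), msd = ens, fit = fit, fits = fits)
  }
}
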
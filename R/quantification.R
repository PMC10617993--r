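#' Cell-cycle correction factors
#'
#' Stage-dependent multipliers accounting for genome duplication through
#' S-phase when converting DAPI intensity fractions to base pairs:
#' 1.0 (G1), 1.05 (early S), 1.25 (mid S), 1.77 (late S), 2.0 (G2).
#'
#' @param stage one of `"G1"`, `"Se"`, `"Sm"`, `"SL"`, `"G2"` (early-,
#'   mid-, late-S).
#' @return the correction factor `C` (dimensionless scalar).
#' @export
cell_cycle_factor <- function(stage = c("G1", "Se", "Sm", "SL", "G2")) {
  stage <- match.arg(stage)
  c(G1 = 1.0, Se = 1.05, Sm = 1.25, SL = 1.77, G2 = 2.0)[[stage]]
}

#' Genome sizes of the cell lines used (bp)
#'
#' HeLa (hypertriploid): 9.682e9 bp; IMR90 (normal diploid): 6.37e9 bp.
#' @format named numeric vector.
#' @export
genome_sizes <- c(HeLa = 9.682e9, IMR90 = 6.37e9)

#' DNA content of labeled foci from DAPI intensity fractions
#'
#' For each labeled focus, the summed DAPI intensity inside the focus mask
#' (`I_RFi`) over the summed DAPI intensity of the whole nucleus
#' (`I_DNA_total`) gives the genome fraction held by the focus; the DNA
#' amount is `dna_bp = (I_RFi / I_DNA_total) * C * GS_bp` with the stage
#' correction factor `C` and genome size `GS_bp`.
#'
#' @param nucleus_mask logical matrix of the nucleus.
#' @param foci_masks list of logical matrices (each a subset of the
#'   nucleus mask).
#' @param dapi_image numeric matrix of background-corrected DAPI
#'   intensities.
#' @param stage cell-cycle stage (see [cell_cycle_factor()]).
#' @param GS_bp genome size in base pairs (> 0).
#' @return data frame: `focus, I_RFi, I_DNA_total, fraction, C, GS_bp,
#'   dna_bp`.
#' @export
dna_per_focus <- function(nucleus_mask, foci_masks, dapi_image, stage,
                          GS_bp) {
  if (GS_bp <= 0) stop_param("GS_bp must be > 0")
  if (!all(dim(nucleus_mask) == dim(dapi_image))) stop_param("mask/image shape mismatch")
  C <- cell_cycle_factor(stage)
  nucleus_mask <- nucleus_mask > 0
  I_total <- sum(dapi_image[nucleus_mask])
  if (I_total == 0) stop_param("total nuclear DAPI intensity is zero")
  rows <- lapply(seq_along(foci_masks), function(i) {
    fm <- foci_masks[[i]] > 0
    if (any(fm & !nucleus_mask)) stop_param("focus %d extends outside the nucleus mask", i)
    I_rf <- sum(dapi_image[fm])
    data.frame(focus = i, I_RFi = I_rf, I_DNA_total = I_total,
               fraction = I_rf / I_total, C = C, GS_bp = GS_bp,
               dna_bp = I_rf / I_total * C * GS_bp)
  })
  do.call(rbind, rows)
}

#' Modal bin of a DNA-content distribution
#'
#' Histogram utility reporting the modal bin plus its right neighbor
#' ("mode + 1 bin") of a per-focus DNA-content distribution.
#'
#' @param dna_bp numeric vector of per-focus DNA amounts (bp).
#' @param bin_bp bin width in bp (default 100 kbp).
#' @return list: `mode_bin` (`c(lo, hi)` in bp), `mode_plus1`
#'   (`c(lo, hi)` spanning the modal and next bin), `counts`, `breaks`.
#' @export
dna_content_mode <- function(dna_bp, bin_bp = 1e5) {
  if (length(dna_bp) == 0) stop_param("no DNA content values")
  breaks <- seq(0, (ceiling(max(dna_bp) / bin_bp) + 1) * bin_bp, by = bin_bp)
  h <- graphics::hist(dna_bp, breaks = breaks, plot = FALSE)
  i <- which.max(h$counts)
  list(mode_bin = c(breaks[i], breaks[i + 1]),
       mode_plus1 = c(breaks[i], breaks[min(i + 2, length(breaks))]),
       counts = h$counts, breaks = breaks)
}

#' Coefficient-of-variation accumulation series
#'
#' For each time point, the coefficient of variation `cV = sigma / mu`
#' (population standard deviation over mean) of the intensities within the
#' segmented signal region reports focal protein accumulation contrast.
#' Values are normalized to the first time point,
#' `cv_norm(t) = cV(t) / cV(t0)`, and optionally divided by a control
#' condition's normalized series at matched times.
#'
#' @param stack an [image_stack] time series (>= 2 time points).
#' @param masks logical matrix applied at every time point, or a list of
#'   one mask per time point.
#' @param channel channel index.
#' @param control optional `accumulation_series` of the control condition.
#' @return object of class `accumulation_series`: data frame fields
#'   `times_s, cv, cv_norm` (+ `control_norm` when a control is given),
#'   and a `degenerate` flag marking all-constant input (`cv = 0`).
#' @export
accumulation_cv <- function(stack, masks, channel = 1L, control = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack$channels[[channel]]
  nt <- dim(ch)[3]
  if (nt < 2) stop_param("need at least 2 time points")
  if (!is.list(masks)) masks <- rep(list(masks), nt)
  if (length(masks) != nt) stop_param("need one mask per time point")
  cv <- numeric(nt)
  for (t in seq_len(nt)) {
    m <- masks[[t]] > 0
    if (!any(m)) stop_param("mask empty at time point %d", t)
    v <- ch[, , t][m]
    mu <- mean(v)
    if (mu == 0) stop_param("mean intensity is zero at time point %d", t)
    cv[t] <- pop_sd(v) / mu
  }
  degenerate <- cv[1] == 0
  cv_norm <- if (degenerate) rep(NA_real_, nt) else cv / cv[1]
  dt <- stack$frame_interval_s
  times <- (seq_len(nt) - 1) * ifelse(is.na(dt), 1, dt)
  out <- list(times_s = times, cv = cv, cv_norm = cv_norm,
              degenerate = degenerate)
  if (!is.null(control)) {
    stopifnot(inherits(control, "accumulation_series"))
    if (length(control$cv_norm) != nt) stop_param("control series length mismatch")
    out$control_norm <- cv_norm / control$cv_norm
  }
  structure(out, class = "accumulation_series")
}

#' @export
print.accumulation_series <- function(x, ...) {
  cat(sprintf("<accumulation_series> %d time points, cV(t0) = %.4g%s\n",
              length(x$cv), x$cv[1],
              if (x$degenerate) " [degenerate: zero contrast]" else ""))
  invisible(x)
}
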
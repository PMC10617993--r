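#' Segment nuclei by threshold + watershed and filter by shape
#'
#' Intensity thresholding, watershed splitting of touching nuclei (seeds
#' from the distance transform), then per-object area and circularity
#' (`4*pi*A/P^2`, perimeter by a four-direction Crofton estimate) with
#' area and circularity filters to remove segmentation artifacts.
#'
#' @param dapi 2D numeric matrix.
#' @param intensity_threshold manual threshold; `NULL` for Otsu.
#' @param min_area_um2,max_area_um2 area window (um^2).
#' @param min_circularity minimal circularity (0-1).
#' @param pixel_size_um pixel size.
#' @return list: `records` data frame (`label, area_um2, circularity,
#'   cx_um, cy_um, total_dapi_intensity, mean_dapi_intensity`), `labels`
#'   (integer label matrix, relabeled after filtering).
#' @export
segment_nuclei_watershed <- function(dapi, intensity_threshold = NULL,
                                     min_area_um2 = 20, max_area_um2 = Inf,
                                     min_circularity = 0.7,
                                     pixel_size_um = 1) {
  dapi <- as_frame(dapi)
  if (!is.matrix(dapi) || length(dapi) == 0) stop_param("dapi must be a non-empty matrix")
  if (is.null(intensity_threshold)) {
    rng <- range(dapi)
    if (diff(rng) == 0) {
      return(list(records = empty_nucleus_records(),
                  labels = matrix(0L, nrow(dapi), ncol(dapi))))
    }
    norm <- (dapi - rng[1]) / diff(rng)
    intensity_threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  bin <- dapi > intensity_threshold
  if (!any(bin)) {
    return(list(records = empty_nucleus_records(),
                labels = matrix(0L, nrow(dapi), ncol(dapi))))
  }
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- matrix(as.integer(EBImage::imageData(ws)), nrow(dapi), ncol(dapi))

  records <- list()
  out_labels <- matrix(0L, nrow(dapi), ncol(dapi))
  new_label <- 0L
  for (l in seq_len(max(labm))) {
    m <- labm == l
    npx <- sum(m)
    area <- npx * pixel_size_um^2
    if (area < min_area_um2 || area > max_area_um2) next
    per <- crofton_perimeter(m) * pixel_size_um
    circ <- 4 * pi * area / per^2
    if (circ < min_circularity) next
    new_label <- new_label + 1L
    out_labels[m] <- new_label
    ij <- which(m, arr.ind = TRUE)
    records[[new_label]] <- data.frame(
      label = new_label, area_um2 = area, circularity = circ,
      cx_um = px_to_um(mean(ij[, 2]), pixel_size_um),
      cy_um = px_to_um(mean(ij[, 1]), pixel_size_um),
      total_dapi_intensity = sum(dapi[m]),
      mean_dapi_intensity = mean(dapi[m]))
  }
  list(records = if (length(records)) do.call(rbind, records) else empty_nucleus_records(),
       labels = out_labels)
}

empty_nucleus_records <- function() {
  data.frame(label = integer(0), area_um2 = numeric(0), circularity = numeric(0),
             cx_um = numeric(0), cy_um = numeric(0),
             total_dapi_intensity = numeric(0), mean_dapi_intensity = numeric(0))
}

# One level of the a-trous (stationary) wavelet transform with the cubic
# B3-spline kernel [1,4,6,4,1]/16; at level j the kernel taps are spaced
# 2^(j-1) pixels apart. Separable convolution with replicated borders.
atrous_smooth <- function(img, level) {
  h <- c(1, 4, 6, 4, 1) / 16
  spacing <- 2^(level - 1)
  offs <- c(-2, -1, 0, 1, 2) * spacing
  ny <- nrow(img); nx <- ncol(img)
  tmp <- matrix(0, ny, nx)
  for (k in seq_along(offs)) {
    rows <- pmin(pmax(seq_len(ny) + offs[k], 1), ny)
    tmp <- tmp + h[k] * img[rows, , drop = FALSE]
  }
  out <- matrix(0, ny, nx)
  for (k in seq_along(offs)) {
    cols <- pmin(pmax(seq_len(nx) + offs[k], 1), nx)
    out <- out + h[k] * tmp[, cols, drop = FALSE]
  }
  out
}

#' Segment foci with the a-trous wavelet transform
#'
#' B3-spline a-trous decomposition of the image; the detail (wavelet)
#' plane at the chosen level is thresholded at `k_sigma` times a robust
#' noise estimate (`1.4826 * MAD` of the first detail plane), connected
#' components become foci, and only foci inside the nuclear areas are
#' kept. The threshold is noise-relative, so foci counts are invariant to
#' global multiplicative intensity changes.
#'
#' @param image 2D numeric matrix (EdU or replication-protein channel).
#' @param nucleus_labels integer label matrix from
#'   [segment_nuclei_watershed()].
#' @param level wavelet scale index (>= 1); spots of radius ~`2^level`
#'   pixels respond strongest.
#' @param k_sigma threshold multiplier (default 3).
#' @param min_spot_px minimal focus area in pixels.
#' @return list: `per_nucleus` data frame (`label, foci_count,
#'   total_foci_intensity, mean_foci_intensity, total_nuclear_intensity`),
#'   `foci_labels` (label matrix of accepted foci).
#' @export
wavelet_foci <- function(image, nucleus_labels, level = 2, k_sigma = 3,
                         min_spot_px = 2) {
  image <- as_frame(image)
  if (level < 1) stop_param("level must be >= 1")
  max_level <- floor(log2(min(dim(image)) / 4))
  if (level > max_level) stop_param("level %d exceeds decomposition depth %d for this image",
                                    level, max_level)
  a_prev <- image
  w1 <- NULL
  for (j in seq_len(level)) {
    a_j <- atrous_smooth(a_prev, j)
    w_j <- a_prev - a_j
    if (j == 1) w1 <- w_j
    a_prev <- a_j
  }
  sigma <- 1.4826 * stats::median(abs(w1 - stats::median(w1)))
  thr <- k_sigma * sigma
  bin <- w_j > thr
  bin[nucleus_labels == 0] <- FALSE  # keep only foci inside nuclei
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  if (max(labm) > 0) {
    sizes <- tabulate(labm[labm > 0], nbins = max(labm))
    small <- which(sizes < min_spot_px)
    if (length(small)) labm[labm %in% small] <- 0L
  }

  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  per <- lapply(labs, function(l) {
    nm <- nucleus_labels == l
    fm <- labm > 0 & nm
    fids <- unique(labm[fm])
    data.frame(label = l,
               foci_count = length(fids),
               total_foci_intensity = sum(image[fm]),
               mean_foci_intensity = if (any(fm)) mean(image[fm]) else 0,
               total_nuclear_intensity = sum(image[nm]),
               mean_nuclear_intensity = mean(image[nm]))
  })
  list(per_nucleus = if (length(per)) do.call(rbind, per) else
         data.frame(label = integer(0), foci_count = integer(0),
                    total_foci_intensity = numeric(0),
                    mean_foci_intensity = numeric(0),
                    total_nuclear_intensity = numeric(0),
                    mean_nuclear_intensity = numeric(0)),
       foci_labels = labm)
}

#' S-phase gating specification
#'
#' EdU focus-count thresholds identifying S-phase nuclei: 50 for control
#' samples and 55 for aphidicolin-treated samples (boundary inclusive:
#' a count equal to the threshold gates as S-phase).
#'
#' @param edu_foci_threshold_control,edu_foci_threshold_treated counts
#'   (>= 0).
#' @return object of class `gate_spec`.
#' @export
gate_spec <- function(edu_foci_threshold_control = 50,
                      edu_foci_threshold_treated = 55) {
  if (edu_foci_threshold_control < 0 || edu_foci_threshold_treated < 0) {
    stop_param("thresholds must be >= 0")
  }
  structure(list(edu_foci_threshold_control = edu_foci_threshold_control,
                 edu_foci_threshold_treated = edu_foci_threshold_treated),
            class = "gate_spec")
}

#' Gate S-phase nuclei by EdU focus count
#'
#' A nucleus is S-phase iff its EdU focus count is `>=` the threshold for
#' its condition. The partition is exhaustive and disjoint.
#'
#' @param records data frame with an `edu_foci_count` column.
#' @param gate a [gate_spec].
#' @param condition `"control"` or `"treated"`.
#' @return `records` with a logical `is_sphase_gated` column added.
#' @export
gate_sphase <- function(records, gate = gate_spec(),
                        condition = c("control", "treated")) {
  condition <- match.arg(condition)
  if (!"edu_foci_count" %in% names(records)) {
    stop_param("records lack an edu_foci_count column (EdU channel missing)")
  }
  thr <- if (condition == "control") gate$edu_foci_threshold_control
         else gate$edu_foci_threshold_treated
  records$is_sphase_gated <- records$edu_foci_count >= thr
  records
}

#' Fraction of EdU-positive nuclei
#'
#' Nuclei with mean EdU intensity strictly greater than the background
#' (measured on an EdU-free, stained negative control) count as
#' EdU-positive.
#'
#' @param records data frame with a `mean_edu_intensity` column.
#' @param background_mean_intensity background level (>= 0).
#' @return the EdU-positive fraction.
#' @export
edu_positive_fraction <- function(records, background_mean_intensity) {
  if (background_mean_intensity < 0) stop_param("background must be >= 0")
  if (NROW(records) == 0) stop_param("no records; EdU-positive fraction undefined")
  mean(records$mean_edu_intensity > background_mean_intensity)
}

#' Two-sided Wilcoxon rank-sum comparison of two conditions
#'
#' Mann-Whitney rank-sum test with midranks for ties. For small samples
#' the null distribution of the rank sum is enumerated exactly over all
#' group assignments (ties included); for larger samples the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param exact_max_comb enumerate exactly when `choose(n_a + n_b, n_a)`
#'   is at most this (default 50000, covering n <= 8 per group and more).
#' @return list: `statistic` (Mann-Whitney U of sample_a), `W` (rank sum),
#'   `p_value`, `method`.
#' @export
compare_conditions <- function(sample_a, sample_b, exact_max_comb = 50000) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0 || nb == 0) stop_param("both samples must be non-empty")
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)  # midranks
  W <- sum(rk[seq_len(na)])
  U <- W - na * (na + 1) / 2
  n <- na + nb
  if (choose(n, na) <= exact_max_comb) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(rk[combs], nrow = na))
    mu <- na * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = U, W = W, p_value = p, method = "exact_enumeration"))
  }
  mu <- na * (n + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z_num <- W - mu
  cc <- sign(z_num) * 0.5
  z <- (z_num - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = U, W = W, p_value = min(1, p), method = "normal_approximation")
}
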
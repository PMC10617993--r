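test_that("watershed splits touching nuclei into separate labels", {
  img <- matrix(0, 120, 120)
  img[disk_mask(120, 120, 60, 45, 25)] <- 100
  img[disk_mask(120, 120, 60, 85, 25)] <- 100   # centers 40 px apart, overlap
  seg <- segment_nuclei_watershed(img, intensity_threshold = 50,
                                  min_area_um2 = 100, min_circularity = 0.5,
                                  pixel_size_um = 1)
  expect_equal(nrow(seg$records), 2)
  one_disk <- pi * 25^2
  for (a in seg$records$area_um2) expect_lt(abs(a / one_disk - 1), 0.10)
})

test_that("a single disk has circularity within 5% of 1", {
  img <- matrix(0, 100, 100)
  img[disk_mask(100, 100, 50, 50, 30)] <- 10
  seg <- segment_nuclei_watershed(img, intensity_threshold = 5,
                                  min_area_um2 = 10, min_circularity = 0,
                                  pixel_size_um = 1)
  expect_equal(nrow(seg$records), 1)
  expect_lt(abs(seg$records$circularity - 1), 0.05)
})

test_that("elongated objects are removed by the circularity filter", {
  img <- matrix(0, 100, 100)
  img[45:55, 10:90] <- 10         # 11 x 81 bar, circularity ~0.4
  img[disk_mask(100, 100, 20, 20, 12)] <- 10
  seg_all <- segment_nuclei_watershed(img, intensity_threshold = 5,
                                      min_area_um2 = 10, min_circularity = 0,
                                      pixel_size_um = 1)
  bar_circ <- min(seg_all$records$circularity)
  expect_lt(bar_circ, 0.7)
  seg <- segment_nuclei_watershed(img, intensity_threshold = 5,
                                  min_area_um2 = 10, min_circularity = 0.7,
                                  pixel_size_um = 1)
  expect_equal(nrow(seg$records), 1)
  expect_gt(min(seg$records$circularity), 0.7)
})

test_that("blank nuclei contain zero wavelet foci", {
  img <- matrix(rnorm(100 * 100, 50, 1), 100, 100)
  labels <- matrix(0L, 100, 100)
  labels[disk_mask(100, 100, 50, 50, 30)] <- 1L
  wf <- wavelet_foci(img, labels, level = 2)
  expect_equal(wf$per_nucleus$foci_count, 0)
})

test_that("sixty well-separated rendered spots are counted exactly", {
  ny <- 200; nx <- 200
  labels <- matrix(0L, ny, nx); labels[10:190, 10:190] <- 1L
  pts <- cbind(rep(seq(20, 180, 16), times = 6), rep(seq(20, 100, 16), each = 11))[1:60, ]
  img <- chromdyn:::render_spots(matrix(0, ny, nx), pts[, 1], pts[, 2],
                                 list(pixel_size_um = 1, psf_sigma_um = 1),
                                 amplitudes = rep(100, 60))
  set.seed(13)
  img <- img + matrix(rnorm(ny * nx, 20, 1), ny, nx)
  wf <- wavelet_foci(img, labels, level = 2)
  expect_equal(wf$per_nucleus$foci_count, 60)
  # multiplicative intensity changes leave the count unchanged
  wf2 <- wavelet_foci(img * 6.5, labels, level = 2)
  expect_equal(wf2$per_nucleus$foci_count, 60)
})

test_that("foci outside every nucleus are excluded", {
  ny <- 120; nx <- 120
  labels <- matrix(0L, ny, nx)
  labels[disk_mask(ny, nx, 40, 40, 25)] <- 1L
  img <- chromdyn:::render_spots(matrix(0, ny, nx),
                                 c(40, 100), c(40, 100),  # one inside, one outside
                                 list(pixel_size_um = 1, psf_sigma_um = 1.2),
                                 amplitudes = c(100, 100))
  set.seed(14)
  img <- img + matrix(rnorm(ny * nx, 10, 1), ny, nx)
  wf <- wavelet_foci(img, labels, level = 2)
  expect_equal(wf$per_nucleus$foci_count, 1)
})

test_that("wavelet level must not exceed the decomposition depth", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  labels <- matrix(1L, 64, 64)
  expect_error(wavelet_foci(img, labels, level = 20), "depth")
})

test_that("S-phase gating applies the 50/55 thresholds inclusively", {
  rec <- data.frame(label = 1:4, edu_foci_count = c(49, 50, 54, 55))
  ctrl <- gate_sphase(rec, gate_spec(), "control")
  expect_identical(ctrl$is_sphase_gated, c(FALSE, TRUE, TRUE, TRUE))
  trt <- gate_sphase(rec, gate_spec(), "treated")
  expect_identical(trt$is_sphase_gated, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(gate_sphase(data.frame(label = 1), gate_spec(), "control"),
               "edu_foci_count")
  # partition is exhaustive and disjoint
  expect_equal(sum(ctrl$is_sphase_gated) + sum(!ctrl$is_sphase_gated), nrow(rec))
})

test_that("a synthetic population recovers its S fraction through the gate", {
  rec <- make_population_records(500, 0.4, seed = 91)
  gated <- gate_sphase(rec, gate_spec(), "control")
  phat <- mean(gated$is_sphase_gated)
  expect_lt(abs(phat - 0.4), 1.96 * sqrt(0.4 * 0.6 / 500))
  # gate agrees with truth labels except for law-overlap stragglers
  expect_gt(mean(gated$is_sphase_gated == gated$is_sphase), 0.98)
})

test_that("the EdU-positive fraction uses a strict background comparison", {
  rec <- data.frame(mean_edu_intensity = c(10, 10, 20, 20))
  expect_equal(edu_positive_fraction(rec, 10), 0.5)
  expect_equal(edu_positive_fraction(rec, 25), 0)
  expect_error(edu_positive_fraction(rec[0, ], 10), "undefined|no records")
})

test_that("identical samples give p close to 1", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_conditions(x, x)
  expect_gt(res$p_value, 0.9)
})

test_that("{1,2,3} vs {4,5,6} enumerates to two-sided p = 0.1", {
  res <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$method, "exact_enumeration")
  expect_equal(res$p_value, 0.1)
})

test_that("the exact path matches wilcox.test and enumeration for n <= 8", {
  set.seed(15)
  for (rep in 1:20) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- round(runif(na, 0, 10), 1)
    b <- round(runif(nb, 0, 10) + 1, 1)
    res <- compare_conditions(a, b)
    expect_identical(res$method, "exact_enumeration")
    if (!any(duplicated(c(a, b)))) {
      wt <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(res$p_value, wt$p.value, tolerance = 1e-9)
    }
    # direct enumeration oracle (midranks, all group assignments)
    rk <- rank(c(a, b))
    W <- sum(rk[seq_len(na)])
    mu <- na * (na + nb + 1) / 2
    sums <- colSums(matrix(rk[utils::combn(na + nb, na)], nrow = na))
    p_oracle <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    expect_equal(res$p_value, p_oracle)
  }
})

test_that("normal approximation agrees with the exact distribution at large n", {
  set.seed(16)
  a <- rnorm(20); b <- rnorm(20, 0.5)      # continuous: no ties
  approx <- compare_conditions(a, b)       # C(40,20) forces the normal path
  expect_identical(approx$method, "normal_approximation")
  exact_p <- wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
  expect_lt(abs(approx$p_value / exact_p - 1), 0.05)
  # and the approximation matches wilcox.test's corrected normal p exactly
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, wt$p.value, tolerance = 1e-9)
})

test_that("empty samples are rejected", {
  expect_error(compare_conditions(numeric(0), 1:3), "non-empty")
})
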
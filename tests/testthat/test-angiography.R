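test_that("maximum-intensity projection matches a per-column oracle", {
  cfg <- toy_config(n = 4, n_depth = 8)
  v <- random_volume(4, 8, seed = 31)

  # single bright voxel per column projects to that value
  vals <- array(0, c(4, 4, 8))
  for (i in 1:4) for (j in 1:4) vals[i, j, sample(8, 1)] <- 0.7
  mono <- toy_volume(vals)
  mip <- max_intensity_projection(mono, array(TRUE, c(4, 4, 8)))
  expect_equal(unique(as.vector(mip$image)), 0.7)

  # masked-out columns project to zero (interval mask path)
  top <- matrix(2L, 4, 4)
  bot <- matrix(6L, 4, 4)
  bot[1, 1] <- 0L
  m <- layer_mask(top, bot, c(4, 4, 8), "superficial_retina")
  got <- max_intensity_projection(v, m)
  expect_equal(got$image[1, 1], 0)
  arr <- as.array(m)
  for (i in 1:4) for (j in 1:4) {
    want <- if (any(arr[i, j, ])) max(v$intensities[i, j, arr[i, j, ]]) else 0
    expect_equal(got$image[i, j], want)
  }
  expect_error(max_intensity_projection(v, array(FALSE, c(4, 4, 8))), "empty")
})

test_that("the threshold maximizes between-class variance and separates classes", {
  withr::local_seed(8)
  x <- matrix(c(rnorm(6000, 0.25, 0.05), rnorm(4000, 0.75, 0.05)), 100, 100)
  x <- pmin(pmax(x, 0), 1)
  ours <- otsu_threshold(x)
  # exhaustive continuous sweep of the between-class-variance objective
  cand <- seq(0.05, 0.95, by = 0.001)
  bcv <- vapply(cand, function(t) {
    w0 <- mean(x <= t)
    if (w0 < 1e-9 || w0 > 1 - 1e-9) return(0)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, numeric(1))
  expect_lt(abs(ours - cand[which.max(bcv)]), 0.01)
  expect_error(otsu_threshold(matrix(0.5, 5, 5)), "constant")

  # clean two-level image: exact recovery through binarize_vessels
  img <- matrix(0, 60, 60)
  img[, 1:30] <- 1
  a <- enface_angiogram(img, 50, "SS")
  bin <- binarize_vessels(a)
  expect_equal(bin, img > 0.5, ignore_attr = TRUE)
  expect_error(binarize_vessels(enface_angiogram(matrix(1, 10, 10), 50, "SS")),
               "constant")
})

test_that("binarization misclassifies under 1% of well-separated noisy pixels", {
  withr::local_seed(21)
  truth <- matrix(runif(300 * 300) < 0.45, 300, 300)
  img <- ifelse(truth, 0.8, 0.2) + rnorm(300 * 300, 0, 0.05)
  a <- enface_angiogram(pmax(img, 0), 10, "SS")
  bin <- binarize_vessels(a)
  expect_lt(mean(bin != truth), 0.01)
})

test_that("binarization is invariant under monotone intensity rescaling", {
  withr::local_seed(13)
  truth <- matrix(runif(200 * 200) < 0.4, 200, 200)
  img <- pmax(ifelse(truth, 0.9, 0.15) + rnorm(4e4, 0, 0.04), 0)
  a1 <- enface_angiogram(img, 10, "SS")
  a2 <- enface_angiogram(3.7 * img + 11, 10, "SS")     # affine
  a3 <- enface_angiogram(sqrt(img / max(img)), 10, "SS")  # monotone nonlinear
  b1 <- binarize_vessels(a1)
  expect_equal(b1, binarize_vessels(a2), ignore_attr = TRUE)
  expect_equal(b1, binarize_vessels(a3), ignore_attr = TRUE)
})

test_that("registration recovers known shifts and rejects unrelated images", {
  pat <- vascular_pattern(6, fov_mm = 3.2)
  cfg_ss <- get_scan_config("SS", "3x3mm")
  base <- render_angiogram(pat, cfg_ss, seed = 2)

  # identical fields: zero shift, ROI centred on the FAZ
  a_sd <- enface_angiogram(base$image, 10, "SD", pattern = "3x3mm")
  reg0 <- register_angiograms(a_sd, base)
  expect_equal(unname(reg0$translation_px), c(0, 0))
  expect_gt(reg0$ncc_peak, 0.98)
  expect_lt(sqrt(sum(reg0$center_mm^2)), 0.1)
  expect_equal(reg0$radius_mm, 1.5 - max(abs(reg0$center_mm)), tolerance = 0.05)

  # a copy shifted by (5, 3) pixels is recovered within one pixel
  shifted <- octapair:::shift_matrix(base$image, 5, 3, fill = 0.15)
  reg <- register_angiograms(a_sd, enface_angiogram(shifted, 10, "SS",
                                                    pattern = "3x3mm"))
  expect_lte(abs(reg$translation_px[1] - 5), 1)
  expect_lte(abs(reg$translation_px[2] - 3), 1)

  # two unrelated noise fields cannot be registered
  withr::local_seed(2)
  n1 <- enface_angiogram(matrix(runif(300^2), 300, 300), 10, "SD")
  n2 <- enface_angiogram(matrix(runif(300^2), 300, 300), 10, "SS")
  expect_error(register_angiograms(n1, n2), "Registration failure")
  expect_error(register_angiograms(base, base), "must be the SD image")
})

test_that("FAZ detection finds the avascular zone or falls back gracefully", {
  pat <- vascular_pattern(9, fov_mm = 3.2, faz_radius_mm = 0.25)
  a <- render_angiogram(pat, get_scan_config("SS", "3x3mm"), seed = 5)
  bin <- binarize_vessels(a)
  faz <- exclude_faz(bin, spacing_um = 10)
  expect_false(attr(faz, "fallback"))
  expect_lt(abs(attr(faz, "area_mm2") - pi * 0.25^2), 0.1 * pi * 0.25^2)
  expect_false(any(faz & bin))

  # no central gap: the fixed-radius fallback engages
  withr::local_seed(33)
  dense <- matrix(runif(200 * 200) < 0.7, 200, 200)
  dense[100, 100] <- TRUE
  expect_warning(fz <- octapair:::find_faz(dense, 10), "fallback")
  expect_true(attr(fz, "fallback"))
  expect_false(any(fz & dense))
})

test_that("vessel density is the vessel fraction of ROI minus FAZ", {
  roi <- structure(list(center_mm = c(0, 0), radius_mm = 0.5, spacing_um = 10,
                        translation_mm = c(0, 0)), class = "common_roi")
  all_vessel <- matrix(TRUE, 120, 120)
  no_faz <- matrix(FALSE, 120, 120)
  expect_equal(vessel_density(all_vessel, roi, no_faz)$density_percent, 100)

  # exactly half of the ROI pixels vessel: left half TRUE
  half <- matrix(FALSE, 120, 120)
  half[1:60, ] <- TRUE
  expect_equal(vessel_density(half, roi, no_faz)$density_percent, 50, tolerance = 1)

  # ROI swallowed by the FAZ leaves an empty denominator
  all_faz <- matrix(TRUE, 120, 120)
  expect_error(vessel_density(half, roi, all_faz), "empty")
  expect_error(vessel_density(half, roi, matrix(FALSE, 60, 60)), "dimensions")
})
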
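test_that("geometry construction honours ordering and the analytic volume", {
  g <- build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 0.5, b_mm = 0.5, c_mm = 0.2)
  ))
  expect_equal(g$analytic_csv_mm3, 0.1047198, tolerance = 1e-6)

  cfg <- toy_config(n = 40, n_depth = 300)
  for (s in 1:5) {
    gj <- build_geometry(geometry_params(
      dome = list(center_mm = c(0.1, -0.2), a_mm = 0.7, b_mm = 0.5, c_mm = 0.3)
    ), seed = s)
    b <- boundary_surfaces_for(gj, cfg)
    expect_true(all(b$ILM <= b$IPL & b$IPL <= b$OPL & b$OPL <= b$ISOS &
                      b$ISOS <= b$RPE & b$RPE <= b$BM))
    # gap equals dome height at the apex
    h_apex <- max(b$RPE - b$ISOS)
    expect_equal(h_apex, 300, tolerance = 2)
  }

  # flat case: zero dome height means no IS/OS-RPE separation anywhere
  flat <- build_geometry(geometry_params())
  bf <- boundary_surfaces_for(flat, cfg)
  expect_true(all(bf$RPE - bf$ISOS == 0))
  expect_equal(mask_voxel_count(csr_mask(bf, 10, cfg)), 0L)

  expect_error(build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 0.5, b_mm = 0.5, c_mm = 0.5)
  )), "OPL")
  expect_error(build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 2, b_mm = 2, c_mm = 0.2)
  ), strict = TRUE), "outside")
})

quiet_model <- function(device, ...) {
  device_model(device, noise_sd = 0, acq_jitter_sd_deep_retina = 0,
               acq_jitter_sd_retina = 0, acq_jitter_sd_deep_tissue = 0, ...)
}

test_that("the forward model reduces to its analytic limits", {
  cfg <- toy_config(n = 10, n_depth = 40, axial_spacing_um = 25)
  uniform <- geometry_params(
    reflectivity = c(vitreous = 0.5, superficial = 0.5, deep = 0.5,
                     outer = 0.5, fluid = 0.5, rpe = 0.5, sattler = 0.5,
                     haller = 0.5, sclera = 0.5)
  )
  g <- build_geometry(uniform)

  # no attenuation, no roll-off, no noise: constant volume
  m0 <- quiet_model("SS", rolloff_per_mm = 0, tissue_attenuation_per_mm = 0)
  v0 <- render_volume(g, m0, cfg, seed = 1)
  expect_equal(unique(as.vector(v0$intensities)), 0.5)

  # pure roll-off: each column decays exactly as exp(-rate * z)
  m1 <- quiet_model("SS", rolloff_per_mm = 0.8, tissue_attenuation_per_mm = 0)
  v1 <- render_volume(g, m1, cfg, seed = 1)
  col <- v1$intensities[4, 7, ]
  expect_true(all(diff(col) < 0))
  z_mm <- (seq_len(cfg$n_depth) - 1) * cfg$axial_spacing_um / 1000
  expect_equal(col, float32_snap(0.5 * exp(-0.8 * z_mm)), tolerance = 1e-7)
})

test_that("rendering is deterministic in the seed", {
  cfg <- toy_config(n = 12, n_depth = 40, axial_spacing_um = 25)
  g <- build_geometry(geometry_params())
  m <- default_device_models()$SS
  v1 <- render_volume(g, m, cfg, seed = 42)
  v2 <- render_volume(g, m, cfg, seed = 42)
  v3 <- render_volume(g, m, cfg, seed = 43)
  expect_identical(v1$intensities, v2$intensities)
  expect_false(identical(v1$intensities, v3$intensities))
  expect_error(render_volume(g, default_device_models()$SD, cfg, seed = 1),
               "scan configuration")
})

test_that("fluid traversal attenuates sub-dome voxels differentially", {
  cfg <- get_scan_config("SS", "3x3mm", n_depth = 280L)
  g <- build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 0.6, b_mm = 0.6, c_mm = 0.3)
  ))
  m <- quiet_model("SS", rolloff_per_mm = 0, tissue_attenuation_per_mm = 0,
                   fluid_excess_attenuation_per_mm = 2)
  v <- render_volume(g, m, cfg, seed = 1)
  b <- boundary_surfaces_for(g, cfg)
  k_sat <- unique(as.vector(octapair:::idx_first_above(b$BM + 50, 5)))
  center <- c(150, 150)
  edge <- c(5, 5)
  ratio <- v$intensities[center[1], center[2], k_sat] /
    v$intensities[edge[1], edge[2], k_sat]
  gap_mm <- (b$RPE[center[1], center[2]] - b$ISOS[center[1], center[2]]) / 1000
  expect_equal(ratio, as.numeric(float32_snap(exp(-2 * gap_mm))), tolerance = 1e-4)
})

test_that("with identical ideal optics the devices agree layer by layer", {
  models <- list(SD = quiet_model("SD", rolloff_per_mm = 0,
                                  tissue_attenuation_per_mm = 0),
                 SS = quiet_model("SS", rolloff_per_mm = 0,
                                  tissue_attenuation_per_mm = 0))
  g <- build_geometry(geometry_params())
  rows <- list()
  for (dev in c("SD", "SS")) {
    cfg <- get_scan_config(dev, "3x3mm", n_depth = 280L)
    b <- boundary_surfaces_for(g, cfg)
    v <- render_volume(g, models[[dev]], cfg, seed = 9)
    v$subject_id <- "S01"
    nv <- normalize_volume(v)
    for (ly in c("superficial_retina", "deep_retina", "sattler", "haller")) {
      rows[[length(rows) + 1L]] <- layer_signal_strength(nv, slab_mask(b, ly, cfg))
    }
  }
  st <- dplyr::bind_rows(rows)
  ds <- signal_strength_difference(st[st$device == "SS", ],
                                   st[st$device == "SD", ])
  expect_lt(max(abs(ds$delta)), 1e-3)
})

test_that("vascular patterns have a clean FAZ and countable vessels", {
  pat <- vascular_pattern(3, fov_mm = 3.2)
  n <- nrow(pat$map)
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * pat$ref_spacing_um / 1000
  inside <- outer(xs^2, xs^2, `+`) <= pat$faz_radius_mm^2
  expect_false(any(pat$map[inside]))
  expect_gt(pat$true_vessel_fraction, 0.2)
  expect_lt(pat$true_vessel_fraction, 0.7)
  expect_identical(pat$map, vascular_pattern(3, fov_mm = 3.2)$map)
})

test_that("angiogram rendering recovers the resampled truth exactly when noiseless", {
  pat <- vascular_pattern(4, fov_mm = 3.2)
  cfg <- get_scan_config("SS", "3x3mm")
  a <- render_angiogram(pat, cfg, seed = 1, vessel_intensity = 1,
                        background_intensity = 0, noise_sd = 0)
  bin <- a$image > 0.5
  g <- octapair:::scan_grid(cfg)
  half_um <- pat$fov_mm * 1000 / 2
  to_ref <- function(p) pmin(pmax(as.integer(round((p * 1000 + half_um) / 2 + 0.5)),
                                  1L), nrow(pat$map))
  truth <- pat$map[to_ref(g$x_mm), to_ref(g$y_mm)]
  expect_identical(bin, truth)

  # density on the 10 um grid tracks the reference-grid fraction
  frac_grid <- mean(truth)
  frac_ref <- mean(pat$map)
  expect_lt(abs(frac_grid - frac_ref), 0.02)
})

test_that("cohorts are reproducible with strictly increasing CSR volumes", {
  c1 <- generate_cohort(2, 2, seed = 77)
  c2 <- generate_cohort(2, 2, seed = 77)
  expect_equal(nrow(c1$subjects), 4)
  expect_equal(nrow(c1$scans), 16)
  expect_identical(dplyr::select(c1$subjects, -geometry),
                   dplyr::select(c2$subjects, -geometry))

  v1 <- render_cohort_volume(c1, "S03", "SS", "3x3mm",
                             config = get_scan_config("SS", "3x3mm", n_depth = 200L))
  v2 <- render_cohort_volume(c2, "S03", "SS", "3x3mm",
                             config = get_scan_config("SS", "3x3mm", n_depth = 200L))
  expect_identical(v1$intensities, v2$intensities)

  c3 <- generate_cohort(0, 6, seed = 12)
  expect_true(all(diff(c3$subjects$analytic_csv_mm3) > 0))
  expect_true(all(c3$subjects$dome_c_mm >= 0.15 & c3$subjects$dome_c_mm <= 0.4))
})
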
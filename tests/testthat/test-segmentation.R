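test_that("slab masks follow the half-open voxel-centre convention", {
  cfg <- toy_config(n = 3, n_depth = 60, axial_spacing_um = 5)
  b <- flat_surfaces(cfg, ILM = 0, IPL = 100, OPL = 150, ISOS = 250,
                     RPE = 250, BM = 270)

  # centres 0, 5, ..., 100 lie in [ILM, IPL]: 21 samples per column
  sup <- slab_mask(b, "superficial_retina", cfg)
  expect_equal(unique(as.vector(sup$bot - sup$top + 1L)), 21L)
  expect_equal(unique(as.vector(sup$top)), 1L)

  # deep retina is (IPL, OPL]: centres 105..150, 10 samples
  deep <- slab_mask(b, "deep_retina", cfg)
  expect_equal(unique(as.vector(deep$top)), 22L)
  expect_equal(unique(as.vector(deep$bot - deep$top + 1L)), 10L)

  # no voxel is claimed by both slabs
  expect_equal(mask_voxel_count(sup) + mask_voxel_count(deep),
               sum(as.array(sup) | as.array(deep)))
  expect_error(slab_mask(b, "ganglion"), "Unknown layer")
})

test_that("choroidal slabs are disjoint, adjacent, and clip with a warning", {
  cfg <- toy_config(n = 4, n_depth = 80)
  b <- flat_surfaces(cfg, ILM = 2, IPL = 100, OPL = 150, ISOS = 250,
                     RPE = 250, BM = 272)
  ch <- choroid_params(t_sattler_um = 60, t_haller_um = 50)
  sat <- slab_mask(b, "sattler", cfg, ch)
  hal <- slab_mask(b, "haller", cfg, ch)
  expect_false(any(as.array(sat) & as.array(hal)))
  expect_true(all(hal$top == sat$bot + 1L))

  # zero-thickness slab yields an empty mask that errors downstream
  sat0 <- slab_mask(b, "sattler", cfg, choroid_params(t_sattler_um = 0))
  expect_equal(mask_voxel_count(sat0), 0L)
  nv <- normalize_volume(toy_volume(array(1, c(4, 4, 80)), config = cfg))
  expect_error(layer_signal_strength(nv, sat0), "empty")

  # a slab reaching past the depth window is clipped and flagged
  expect_warning(
    hal_clip <- slab_mask(b, "haller", cfg, choroid_params(60, 500)),
    "clipped"
  )
  expect_true(hal_clip$clipped)
  expect_equal(max(hal_clip$bot), cfg$n_depth)
})

test_that("the CSR mask marks only genuine IS/OS-RPE separations", {
  cfg <- get_scan_config("SS", "3x3mm")
  healthy <- build_geometry(geometry_params())
  b <- boundary_surfaces_for(healthy, cfg)
  expect_equal(mask_voxel_count(csr_mask(b, 10, cfg)), 0L)

  dome <- build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 0.5, b_mm = 0.3, c_mm = 0.2)
  ))
  bd <- boundary_surfaces_for(dome, cfg)
  m <- csr_mask(bd, 10, cfg)
  expect_gt(mask_voxel_count(m), 0)

  # footprint is the dome ellipse to within one lateral spacing
  footprint <- m$bot >= m$top
  g <- octapair:::scan_grid(cfg)
  idx <- which(footprint, arr.ind = TRUE)
  r2 <- (g$x_mm[idx[, 1]] / 0.5)^2 + (g$y_mm[idx[, 2]] / 0.3)^2
  expect_lte(max(sqrt(r2)), 1 + cfg$lateral_spacing_um / 1000 / 0.3)
  # and every in-ellipse position with gap above threshold is covered
  inside <- outer((g$x_mm / 0.5)^2, (g$y_mm / 0.3)^2, `+`) < 0.9^2
  expect_true(all(footprint[inside]))

  # threshold above the dome height suppresses everything
  expect_equal(mask_voxel_count(csr_mask(bd, 250, cfg)), 0L)
})

test_that("CSV volumetry counts whole voxels in physical units", {
  cfg <- get_scan_config("SS", "3x3mm", n_depth = 12L)
  top <- matrix(1L, 300, 300)
  bot <- matrix(0L, 300, 300)
  bot[1:20, 1:5] <- 10L  # 100 columns x 10 samples = 1000 voxels
  m <- layer_mask(top, bot, c(300, 300, 12), "csr_region")
  res <- measure_csv(m, cfg)
  expect_equal(res$voxel_count, 1000L)
  expect_equal(res$volume_mm3, 1000 * 10 * 10 * 5 * 1e-9)  # 5e-4 mm^3
  expect_true(res$touches_fov_boundary)  # block touches the first row

  empty <- layer_mask(matrix(1L, 300, 300), matrix(0L, 300, 300),
                      c(300, 300, 12), "csr_region")
  expect_equal(measure_csv(empty, cfg)$volume_mm3, 0)
  wrong <- layer_mask(top, bot, c(300, 300, 12), "sattler")
  expect_error(measure_csv(wrong, cfg), "csr_region")
})

test_that("measured CSV approaches the analytic dome volume", {
  g <- build_geometry(geometry_params(
    dome = list(center_mm = c(0, 0), a_mm = 0.5, b_mm = 0.5, c_mm = 0.2)
  ))
  expect_equal(g$analytic_csv_mm3, 2 / 3 * pi * 0.5 * 0.5 * 0.2)

  cfg <- get_scan_config("SS", "3x3mm")
  v <- measure_csv(csr_mask(boundary_surfaces_for(g, cfg), 10, cfg), cfg)
  expect_lt(abs(v$volume_mm3 / g$analytic_csv_mm3 - 1), 0.02)
})

test_that("halving the voxel spacings drives measured CSV toward the analytic value", {
  # a generic (grid-incommensurate) baseline depth, so the coarse-grid error
  # is a genuine discretization offset rather than phase noise
  coarse <- get_scan_config("SD", "6x6mm")
  fine <- scan_config("SD", "6x6mm", 700, 700, 6000 / 700,
                      axial_spacing_um = 2.5, n_depth = 800L)
  for (cm in c(0.103, 0.149, 0.193)) {
    g <- build_geometry(geometry_params(
      ilm_depth_um = 251.1,
      dome = list(center_mm = c(0, 0), a_mm = 0.4, b_mm = 0.4, c_mm = cm)
    ))
    err <- vapply(list(coarse, fine), function(cfg) {
      v <- measure_csv(csr_mask(boundary_surfaces_for(g, cfg), 10, cfg), cfg)
      abs(v$volume_mm3 - g$analytic_csv_mm3)
    }, numeric(1))
    expect_lt(err[2], err[1])
  }
})

test_that("measured CSV is monotone in dome height", {
  cfg <- get_scan_config("SD", "3x3mm")
  prev <- -Inf
  for (cmm in c(0, 0.05, 0.1, 0.2, 0.3, 0.4)) {
    g <- build_geometry(geometry_params(
      dome = list(center_mm = c(0, 0), a_mm = 0.8, b_mm = 0.6, c_mm = cmm)
    ))
    v <- measure_csv(csr_mask(boundary_surfaces_for(g, cfg), 10, cfg), cfg)
    expect_gte(v$volume_mm3, prev)
    prev <- v$volume_mm3
  }
})
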
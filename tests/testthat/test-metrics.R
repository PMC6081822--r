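test_that("normalization divides by the total backscattered signal", {
  v <- toy_volume(array(5, c(2, 2, 2)), config = toy_config(n = 2, n_depth = 2))
  nv <- normalize_volume(v)
  expect_equal(as.vector(nv$values), rep(0.125, 8))
  expect_equal(nv$total_raw_signal, 40)

  vals <- array(0, c(2, 2, 2))
  vals[1, 1, 1] <- 1
  vals[2, 2, 2] <- 3
  nv <- normalize_volume(toy_volume(vals, config = toy_config(n = 2, n_depth = 2)))
  expect_equal(nv$values[1, 1, 1], 0.25)
  expect_equal(nv$values[2, 2, 2], 0.75)

  expect_error(normalize_volume(toy_volume(array(0, c(2, 2, 2)),
                                           config = toy_config(2, 2))),
               "all-zero")
})

test_that("normalized volumes conserve unit total signal", {
  for (s in 1:20) {
    v <- random_volume(n = sample(2:12, 1), n_depth = sample(2:16, 1), seed = s)
    nv <- normalize_volume(v)
    expect_lt(abs(sum(nv$values) - 1), 1e-9)
    expect_gte(min(nv$values), 0)
    expect_lte(max(nv$values), 1)
  }
})

test_that("layer signal strength is the masked mean of normalized signal", {
  cfg <- toy_config(n = 2, n_depth = 2)
  nv <- normalize_volume(toy_volume(array(3, c(2, 2, 2)), config = cfg))
  everything <- array(TRUE, c(2, 2, 2))
  s <- layer_signal_strength(nv, everything)
  expect_equal(s$value, 1 / 8)
  expect_equal(s$voxel_count, 8L)
  expect_equal(s$value_rel, 1)

  # two masked voxels with normalized values 0.1 and 0.3
  vals <- array(0, c(2, 2, 2))
  vals[1, 1, 1] <- 2
  vals[2, 1, 1] <- 6
  vals[1, 2, 2] <- 12
  nv <- normalize_volume(toy_volume(vals, config = cfg))
  m <- array(FALSE, c(2, 2, 2))
  m[1:2, 1, 1] <- TRUE
  s <- layer_signal_strength(nv, m)
  expect_equal(s$layer_sum, 0.4)
  expect_equal(s$voxel_count, 2L)
  expect_equal(s$value, 0.2)

  expect_error(layer_signal_strength(nv, array(FALSE, c(2, 2, 2))), "empty")
  expect_error(layer_signal_strength(nv, array(TRUE, c(2, 2, 3))), "match")
  expect_error(layer_signal_strength(toy_volume(vals, config = cfg), m),
               "normalized")
})

test_that("interval-mask sums match the per-voxel brute-force oracle", {
  for (s in 1:12) {
    cfg <- toy_config(n = sample(3:8, 1), n_depth = sample(4:8, 1))
    v <- random_volume(cfg$n_fast, cfg$n_depth, seed = 100 + s)
    nv <- normalize_volume(v)
    m <- random_interval_mask(cfg, seed = 200 + s)
    got <- layer_signal_strength(nv, m)
    want <- brute_layer_sum(nv$values, as.array(m))
    expect_equal(got$layer_sum, want$sum, tolerance = 1e-13)
    expect_identical(got$voxel_count, want$count)
    expect_equal(got$value, want$sum / want$count, tolerance = 1e-13)
    # dense and interval representations agree
    dense <- layer_signal_strength(nv, as.array(m))
    expect_equal(dense$layer_sum, got$layer_sum, tolerance = 1e-13)
  }
})

test_that("metrics are invariant under raw intensity rescaling", {
  cfg <- toy_config(n = 5, n_depth = 6)
  v1 <- random_volume(5, 6, seed = 1)
  v2 <- scan_volume(v1$intensities * 37.5, cfg)
  m <- random_interval_mask(cfg, seed = 2)
  s1 <- layer_signal_strength(normalize_volume(v1), m)
  s2 <- layer_signal_strength(normalize_volume(v2), m)
  expect_equal(s1$value, s2$value, tolerance = 1e-12)
  expect_equal(s1$value_rel, s2$value_rel, tolerance = 1e-12)
})

test_that("layer sums decompose over disjoint masks", {
  cfg <- toy_config(n = 6, n_depth = 8)
  nv <- normalize_volume(random_volume(6, 8, seed = 3))
  a <- array(FALSE, dim = dim(nv$values))
  b <- array(FALSE, dim = dim(nv$values))
  a[, , 1:3] <- TRUE
  b[, , 6:8] <- TRUE
  su <- layer_signal_strength(nv, a | b)
  sa <- layer_signal_strength(nv, a)
  sb <- layer_signal_strength(nv, b)
  expect_equal(su$layer_sum, sa$layer_sum + sb$layer_sum, tolerance = 1e-12)
  expect_equal(su$voxel_count, sa$voxel_count + sb$voxel_count)
})

test_that("signal differences pair SS and SD measurements by key", {
  row <- function(device, value_rel, layer = "sattler", subj = "S01") {
    tibble::tibble(layer = layer, device = device, pattern = "3x3mm",
                   subject_id = subj, eye_label = "OD", layer_sum = 1,
                   voxel_count = 1L, value = value_rel, value_rel = value_rel)
  }
  expect_equal(signal_strength_difference(row("SS", 0.3), row("SD", 0.3))$delta, 0)
  expect_equal(signal_strength_difference(row("SS", 0.5), row("SD", 0.2))$delta, 0.3)
  expect_error(signal_strength_difference(row("SD", 1), row("SD", 1)), "SS")
  expect_error(
    signal_strength_difference(row("SS", 1), row("SD", 1, subj = "S02")),
    "pair up"
  )
  # per-voxel scale reproduces the plain difference of per-voxel means
  d <- signal_strength_difference(row("SS", 0.5), row("SD", 0.2),
                                  scale = "per_voxel")
  expect_equal(d$delta, 0.3)
})
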
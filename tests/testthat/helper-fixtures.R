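# Small in-code fixtures. Toy scan configurations keep the nominal scan
# width consistent (n * spacing = 3000 um) so they pass the same validation
# as the instrument protocols.

toy_config <- function(n = 4L, n_depth = 8L, device = "SS", pattern = "3x3mm",
                       axial_spacing_um = 5) {
  width <- c(`3x3mm` = 3000, `6x6mm` = 6000)[[pattern]]
  scan_config(device, pattern, n, n, lateral_spacing_um = width / n,
              axial_spacing_um = axial_spacing_um, n_depth = n_depth)
}

toy_volume <- function(values, n = NULL, n_depth = NULL, config = NULL, ...) {
  if (is.null(config)) {
    d <- dim(values)
    config <- toy_config(n = d[1], n_depth = d[3])
  }
  scan_volume(values, config, ...)
}

random_volume <- function(n, n_depth, seed) {
  withr::local_seed(seed)
  vals <- array(runif(n * n * n_depth), dim = c(n, n, n_depth))
  toy_volume(vals)
}

# Flat boundary surfaces at fixed depths (um) on a toy grid.
flat_surfaces <- function(config, ILM = 0, IPL = 100, OPL = 150, ISOS = 250,
                          RPE = 250, BM = 270) {
  m <- function(v) matrix(v, config$n_fast, config$n_slow)
  boundary_surfaces(ILM = m(ILM), IPL = m(IPL), OPL = m(OPL),
                    ISOS = m(ISOS), RPE = m(RPE), BM = m(BM), config = config)
}

# Brute-force per-voxel oracle for layer sums.
brute_layer_sum <- function(values, mask_arr) {
  s <- 0
  cnt <- 0L
  d <- dim(values)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask_arr[i, j, k]) {
      s <- s + values[i, j, k]
      cnt <- cnt + 1L
    }
  }
  list(sum = s, count = cnt)
}

random_interval_mask <- function(config, seed, layer_name = "sattler") {
  withr::local_seed(seed)
  nf <- config$n_fast
  ns <- config$n_slow
  nz <- config$n_depth
  top <- matrix(sample.int(nz, nf * ns, replace = TRUE), nf, ns)
  bot <- matrix(pmin(top + sample.int(nz, nf * ns, replace = TRUE) - 1L, nz), nf, ns)
  layer_mask(top, bot, c(nf, ns, nz), layer_name)
}

# dS-vs-CSV regressions for a CSR-only cohort on the 3x3 mm pattern.
ds_csv_fits <- function(seed, n_csr = 5, noise_sd = 0) {
  coh <- generate_cohort(0, n_csr, seed = seed,
                         device_models = default_device_models(noise_sd))
  rows <- list()
  csvs <- list()
  for (i in seq_len(n_csr)) {
    sid <- coh$subjects$subject_id[i]
    geom <- coh$subjects$geometry[[i]]
    for (dev in c("SD", "SS")) {
      cfg <- get_scan_config(dev, "3x3mm")
      b <- boundary_surfaces_for(geom, cfg)
      seed_i <- coh$scans$scan_seed[coh$scans$subject_id == sid &
                                      coh$scans$device == dev &
                                      coh$scans$pattern == "3x3mm"]
      v <- render_volume(geom, coh$device_models[[dev]], cfg, seed = seed_i,
                         surfaces = b)
      v$subject_id <- sid
      nv <- normalize_volume(v)
      rm(v)
      for (ly in c("deep_retina", "sattler", "haller")) {
        rows[[length(rows) + 1L]] <- layer_signal_strength(nv, slab_mask(b, ly, cfg))
      }
      csvs[[length(csvs) + 1L]] <-
        dplyr::mutate(measure_csv(csr_mask(b, 10, cfg), cfg), subject_id = sid)
    }
  }
  st <- dplyr::bind_rows(rows)
  ds <- signal_strength_difference(st[st$device == "SS", ], st[st$device == "SD", ])
  cv <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(csvs), subject_id),
                         csv = mean(volume_mm3), .groups = "drop")
  m <- dplyr::inner_join(ds, cv, by = "subject_id")
  lapply(split(m, m$layer), function(d) linear_regression(d$csv, d$delta))
}
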
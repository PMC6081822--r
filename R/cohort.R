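#' Generate a paired synthetic cohort
#'
#' Creates `n_normal` healthy subjects and `n_csr` subjects with a central
#' serous detachment, each (virtually) imaged by both devices under both
#' scan patterns. Detachment size grows across the CSR subjects: dome
#' semi-axes run from 0.6 to 1.3 mm and heights from 0.15 to 0.40 mm by
#' default, so the analytic fluid volume spans roughly 0.11-1.4 mm^3, with
#' strictly increasing volume in subject order. Optionally, `n_truncated`
#' extra CSR subjects carry a lesion wide enough (semi-axis 2 mm) to overrun
#' the 3 x 3 mm field of view — the situation in which the small scan
#' pattern under-measures the fluid volume — while still fitting the
#' 6 x 6 mm field.
#'
#' Every subject receives a geometry (with seeded subject-level biological
#' variation; see [geometry_params()]) and a seeded vascular pattern, and
#' every scan a deterministic sub-seed, so the full dataset is reproducible
#' bit-for-bit from the master seed. Images are rendered lazily with
#' [render_cohort_volume()] to keep memory bounded.
#'
#' @param n_normal,n_csr Subject counts (>= 0).
#' @param seed Master seed.
#' @param n_truncated Extra CSR subjects with FOV-overrunning lesions.
#' @param configs Tibble of scan configurations ([builtin_scan_configs()]).
#' @param device_models Named list with `SD` and `SS` [device_model()]s.
#' @param params Baseline [geometry_params()].
#' @param dome_a_mm,dome_c_mm Length-2 ranges of dome semi-axis and height
#'   across the CSR subjects.
#' @return An `octa_cohort`: `$subjects` (one row per subject with ground
#'   truth: `analytic_csv_mm3`, `true_vessel_fraction`, dome parameters,
#'   seeds, `geometry` list-column) and `$scans` (one row per subject x
#'   device x pattern with its `scan_seed`).
#' @export
#' @examples
#' coh <- generate_cohort(2, 2, seed = 1)
#' coh$subjects[, c("subject_id", "group", "analytic_csv_mm3")]
generate_cohort <- function(n_normal = 7, n_csr = 7, seed,
                            n_truncated = 0,
                            configs = builtin_scan_configs(),
                            device_models = default_device_models(),
                            params = geometry_params(),
                            dome_a_mm = c(0.6, 1.3),
                            dome_c_mm = c(0.15, 0.40)) {
  stopifnot(n_normal >= 0, n_csr >= 0, n_truncated >= 0)
  n_total <- n_normal + n_csr + n_truncated
  if (n_total == 0L) abort("Cohort must contain at least one subject.")
  withr::local_seed(as.integer(seed))
  seed_pool <- matrix(sample.int(.Machine$integer.max - 1L, n_total * 2L),
                      ncol = 2L)
  scan_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_total * nrow(configs)),
                       ncol = nrow(configs))

  frac <- function(i, n) if (n <= 1L) 0.5 else (i - 1) / (n - 1)
  subjects <- purrr::map_dfr(seq_len(n_total), function(i) {
    group <- if (i <= n_normal) "normal" else if (i <= n_normal + n_csr) "csr" else "csr_truncated"
    if (group == "normal") {
      dome <- list(center_mm = c(0, 0), a_mm = 0, b_mm = 0, c_mm = 0)
    } else if (group == "csr") {
      t <- frac(i - n_normal, n_csr)
      a <- dome_a_mm[1] + diff(dome_a_mm) * t
      dome <- list(center_mm = c(0, 0), a_mm = a, b_mm = a,
                   c_mm = dome_c_mm[1] + diff(dome_c_mm) * t)
    } else {
      dome <- list(center_mm = c(0, 0), a_mm = 2.0, b_mm = 1.2, c_mm = 0.35)
    }
    p <- params
    p$dome <- dome
    if (group == "csr_truncated") p$subject_jitter$center_mm <- 0
    geom <- build_geometry(p, seed = seed_pool[i, 1L])
    pat_seed <- seed_pool[i, 2L]
    pat <- vascular_pattern(pat_seed)
    tibble(
      subject_id = sprintf("S%02d", i),
      group = group,
      eye_label = if (i %% 2L == 1L) "OD" else "OS",
      subject_seed = seed_pool[i, 1L],
      pattern_seed = pat_seed,
      dome_a_mm = geom$dome$a_mm, dome_b_mm = geom$dome$b_mm,
      dome_c_mm = geom$dome$c_mm,
      analytic_csv_mm3 = geom$analytic_csv_mm3,
      true_vessel_fraction = pat$true_vessel_fraction,
      geometry = list(geom)
    )
  })

  scans <- tidyr::crossing(
    subjects[, c("subject_id", "group")],
    configs[, c("device", "pattern")]
  )
  scans <- dplyr::arrange(scans, .data$subject_id, .data$device, .data$pattern)
  scans$scan_seed <- as.vector(t(scan_seeds))

  structure(
    list(subjects = subjects, scans = scans, configs = configs,
         device_models = device_models, params = params,
         seed = as.integer(seed)),
    class = "octa_cohort"
  )
}

#' @export
print.octa_cohort <- function(x, ...) {
  cat(sprintf(
    "<octa_cohort> %d subjects (%d normal, %d CSR), %d planned scans, seed %d\n",
    nrow(x$subjects), sum(x$subjects$group == "normal"),
    sum(x$subjects$group != "normal"), nrow(x$scans), x$seed
  ))
  invisible(x)
}

cohort_scan_row <- function(cohort, subject_id, device, pattern) {
  row <- cohort$scans[cohort$scans$subject_id == subject_id &
                        cohort$scans$device == device &
                        cohort$scans$pattern == pattern, ]
  if (nrow(row) != 1L) {
    abort(sprintf("No scan planned for %s / %s / %s.", subject_id, device, pattern))
  }
  row
}

#' Render one planned scan of a cohort
#'
#' @param cohort An `octa_cohort`.
#' @param subject_id,device,pattern Identify the scan.
#' @param config Optional [scan_config()] override (e.g. reduced depth).
#' @return A [scan_volume()].
#' @export
render_cohort_volume <- function(cohort, subject_id, device, pattern,
                                 config = NULL) {
  row <- cohort_scan_row(cohort, subject_id, device, pattern)
  geom <- cohort$subjects$geometry[[match(subject_id, cohort$subjects$subject_id)]]
  if (is.null(config)) config <- get_scan_config(device, pattern)
  render_volume(geom, cohort$device_models[[device]], config,
                seed = row$scan_seed)
}

#' Render one subject's en-face angiogram
#'
#' @inheritParams render_cohort_volume
#' @param pattern_obj Optional pre-built [vascular_pattern()] (rebuilt from
#'   the subject's stored seed when `NULL`).
#' @return An [enface_angiogram()].
#' @export
render_cohort_angiogram <- function(cohort, subject_id, device, pattern,
                                    config = NULL, pattern_obj = NULL) {
  row <- cohort_scan_row(cohort, subject_id, device, pattern)
  subj <- cohort$subjects[match(subject_id, cohort$subjects$subject_id), ]
  if (is.null(pattern_obj)) pattern_obj <- vascular_pattern(subj$pattern_seed)
  if (is.null(config)) config <- get_scan_config(device, pattern)
  render_angiogram(pattern_obj, config, seed = row$scan_seed + 1L)
}
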
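#' Pipeline configuration
#'
#' Assembles the single configuration record driving [run_pipeline()]. Any
#' field may be overridden; the resolved configuration is stored in the
#' report (and written beside the tables) for provenance.
#'
#' @param seed Master seed (required for synthetic cohorts).
#' @param n_normal,n_csr,n_truncated Cohort composition.
#' @param patterns Scan patterns to analyse.
#' @param axial_spacing_um,n_depth Depth sampling of all rendered scans.
#' @param noise_sd Additive noise level of both device models.
#' @param device_models Optional full override of
#'   [default_device_models()].
#' @param choroid [choroid_params()].
#' @param min_gap_um IS/OS-RPE gap threshold of [csr_mask()].
#' @param angio Angiography options: `search_px`, `corr_floor`, `levels`,
#'   and `faz` ([faz_params()]).
#' @param delta_scale Scale for [signal_strength_difference()].
#' @param out_dir Optional directory for report tables and the run log.
#' @param verbose Emit per-stage progress messages.
#' @return A named list of class `octa_pipeline_config`.
#' @export
pipeline_config <- function(seed, n_normal = 7, n_csr = 7, n_truncated = 0,
                            patterns = c("3x3mm", "6x6mm"),
                            axial_spacing_um = 5, n_depth = 400L,
                            noise_sd = 0.02, device_models = NULL,
                            choroid = choroid_params(), min_gap_um = 10,
                            angio = list(search_px = 6L, corr_floor = 0.2,
                                         levels = 256L, faz = faz_params()),
                            delta_scale = "relative",
                            out_dir = NULL, verbose = FALSE) {
  structure(
    list(seed = as.integer(seed), n_normal = n_normal, n_csr = n_csr,
         n_truncated = n_truncated, patterns = patterns,
         axial_spacing_um = axial_spacing_um, n_depth = as.integer(n_depth),
         noise_sd = noise_sd, device_models = device_models,
         choroid = choroid, min_gap_um = min_gap_um, angio = angio,
         delta_scale = delta_scale, out_dir = out_dir, verbose = verbose),
    class = "octa_pipeline_config"
  )
}

resolve_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "octa_pipeline_config")) return(config)
  if (!is.list(config)) abort("`config` must be a list, a pipeline_config(), or a YAML path.")
  if (is.null(config$seed)) abort("The pipeline configuration must name a `seed`.")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration keys: %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, config)
}

config_hash <- function(config) {
  # polynomial rolling hash (mod 2^31 - 1) over the deparsed configuration
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full dual-device comparison pipeline
#'
#' Generates (or accepts) a paired cohort and executes the whole analysis:
#' volume normalization, slab masks, per-layer signal strength for both
#' devices and both scan patterns, inter-device signal differences, serous
#' volume (CSV) per CSR subject, registered vessel density, and the group
#' statistics (paired t-tests per layer and for vessel density, ΔS-versus-CSV
#' regressions, and SD-versus-SS CSV agreement with Bland-Altman limits).
#' Identical configuration and seed reproduce the report bit-for-bit.
#'
#' @param config A [pipeline_config()], a named list of its fields, or the
#'   path to a YAML file of them.
#' @param cohort Optional pre-built [generate_cohort()] result; when `NULL`
#'   one is generated from the configuration.
#' @return A `comparison_report` (see [write_report_tables()]).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  cfg <- resolve_pipeline_config(config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  dm <- cfg$device_models %||% default_device_models(noise_sd = cfg$noise_sd)
  if (is.null(cohort)) {
    say("Generating cohort (%d normal, %d CSR, seed %d)",
        cfg$n_normal, cfg$n_csr + cfg$n_truncated, cfg$seed)
    cohort <- generate_cohort(cfg$n_normal, cfg$n_csr, seed = cfg$seed,
                              n_truncated = cfg$n_truncated,
                              device_models = dm)
  }
  layers <- c("superficial_retina", "deep_retina", "sattler", "haller")
  warn_log <- list()
  note_warning <- function(stage, subject, msg) {
    warn_log[[length(warn_log) + 1L]] <<- tibble(
      stage = stage, subject_id = subject, message = msg
    )
  }

  strength_rows <- list()
  csv_rows <- list()
  density_rows <- list()

  for (si in seq_len(nrow(cohort$subjects))) {
    subj <- cohort$subjects[si, ]
    geom <- subj$geometry[[1L]]
    say("Subject %s (%s)", subj$subject_id, subj$group)
    pattern_obj <- vascular_pattern(subj$pattern_seed)
    for (pat in cfg$patterns) {
      for (dev in c("SD", "SS")) {
        scfg <- get_scan_config(dev, pat,
                                axial_spacing_um = cfg$axial_spacing_um,
                                n_depth = cfg$n_depth)
        surfaces <- boundary_surfaces_for(geom, scfg)
        if (isTRUE(attr(surfaces, "truncated"))) {
          note_warning("segmentation", subj$subject_id,
                       sprintf("lesion truncated by the %s field (%s)", pat, dev))
        }
        seed_row <- cohort_scan_row(cohort, subj$subject_id, dev, pat)
        vol <- render_volume(geom, dm[[dev]], scfg, seed = seed_row$scan_seed,
                             surfaces = surfaces, choroid = cfg$choroid)
        vol$subject_id <- subj$subject_id
        vol$eye_label <- subj$eye_label
        nv <- normalize_volume(vol)
        rm(vol)
        for (ly in layers) {
          m <- withCallingHandlers(
            slab_mask(surfaces, ly, scfg, cfg$choroid),
            warning = function(w) {
              note_warning("segmentation", subj$subject_id, conditionMessage(w))
              invokeRestart("muffleWarning")
            }
          )
          row <- layer_signal_strength(nv, m)
          row$group <- subj$group
          strength_rows[[length(strength_rows) + 1L]] <- row
        }
        if (subj$group != "normal") {
          cm <- csr_mask(surfaces, cfg$min_gap_um, scfg)
          cr <- measure_csv(cm, scfg)
          cr$subject_id <- subj$subject_id
          cr$group <- subj$group
          cr$analytic_csv_mm3 <- subj$analytic_csv_mm3
          csv_rows[[length(csv_rows) + 1L]] <- cr
        }
        rm(nv)
      }
      # vessel density on the registered common circular ROI
      angio_seed_sd <- cohort_scan_row(cohort, subj$subject_id, "SD", pat)$scan_seed
      angio_seed_ss <- cohort_scan_row(cohort, subj$subject_id, "SS", pat)$scan_seed
      a_sd <- render_angiogram(pattern_obj,
                               get_scan_config("SD", pat), angio_seed_sd + 1L)
      a_ss <- render_angiogram(pattern_obj,
                               get_scan_config("SS", pat), angio_seed_ss + 1L)
      reg <- register_angiograms(a_sd, a_ss,
                                 search_px = cfg$angio$search_px,
                                 corr_floor = cfg$angio$corr_floor,
                                 faz_config = cfg$angio$faz)
      for (dev in c("SD", "SS")) {
        img <- if (dev == "SD") a_sd else a_ss
        bin <- binarize_vessels(img, reg, levels = cfg$angio$levels)
        faz <- withCallingHandlers(
          exclude_faz(bin, reg, cfg$angio$faz),
          warning = function(w) {
            note_warning("faz", subj$subject_id, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        )
        vd <- vessel_density(bin, reg, faz, device = dev, pattern = pat)
        vd$subject_id <- subj$subject_id
        vd$group <- subj$group
        vd$true_vessel_fraction <- vessel_fraction(pattern_obj, reg$radius_mm)
        vd$ncc_peak <- reg$ncc_peak
        vd$threshold <- attr(bin, "threshold")
        vd$faz_fallback <- isTRUE(attr(faz, "fallback"))
        density_rows[[length(density_rows) + 1L]] <- vd
      }
    }
  }

  strength <- dplyr::bind_rows(strength_rows)
  csv_tab <- dplyr::bind_rows(csv_rows)
  density <- dplyr::bind_rows(density_rows)

  delta_s <- signal_strength_difference(
    dplyr::filter(strength, .data$device == "SS"),
    dplyr::filter(strength, .data$device == "SD"),
    scale = cfg$delta_scale
  )
  delta_s <- dplyr::left_join(
    delta_s,
    strength[strength$device == "SS",
             c("subject_id", "layer", "pattern", "group")],
    by = c("subject_id", "layer", "pattern")
  )

  say("Computing group statistics")
  report <- structure(
    list(
      subjects = dplyr::select(cohort$subjects, -"geometry"),
      signal_strength = strength,
      delta_s = delta_s,
      csv_measurements = csv_tab,
      vessel_density = density,
      signal_tests = summarize_paired_tests(strength, "value_rel"),
      density_tests = summarize_paired_tests(density, "density_percent"),
      ds_csv_regressions = regress_ds_on_csv(delta_s, csv_tab),
      csv_agreement = csv_agreement_stats(csv_tab),
      warnings = dplyr::bind_rows(warn_log),
      metadata = list(seed = cfg$seed, config = unclass(cfg),
                      config_hash = config_hash(unclass(cfg)),
                      n_subjects = nrow(cohort$subjects),
                      patterns = cfg$patterns,
                      package_version = as.character(utils::packageVersion("octapair")))
    ),
    class = "comparison_report"
  )
  report <- flag_fov_outliers(report)
  if (!is.null(cfg$out_dir)) {
    write_report_tables(report, cfg$out_dir)
  }
  report
}

paired_wide <- function(tab, value_col) {
  tidyr::pivot_wider(
    tab[, c("subject_id", "group", "pattern", intersect("layer", names(tab)),
            "device", value_col)],
    names_from = "device", values_from = dplyr::all_of(value_col)
  )
}

summarize_paired_tests <- function(tab, value_col) {
  wide <- paired_wide(tab, value_col)
  keys <- intersect(c("group", "pattern", "layer"), names(wide))
  dplyr::group_modify(dplyr::group_by(wide, dplyr::across(dplyr::all_of(keys))),
    function(d, g) {
      d <- d[complete.cases(d[, c("SD", "SS")]), ]
      if (nrow(d) < 2L || sd(d$SS - d$SD) == 0) {
        return(tibble(n = nrow(d), mean_sd = mean(d$SD), mean_ss = mean(d$SS),
                      sd_sd = sd(d$SD), sd_ss = sd(d$SS),
                      mean_difference = mean(d$SS - d$SD),
                      t_statistic = NA_real_, p_value = NA_real_))
      }
      tt <- paired_t_test(d$SD, d$SS)
      tibble(n = tt$n, mean_sd = mean(d$SD), mean_ss = mean(d$SS),
             sd_sd = sd(d$SD), sd_ss = sd(d$SS),
             mean_difference = tt$mean_difference,
             t_statistic = tt$t_statistic, p_value = tt$p_value)
    }) |> dplyr::ungroup()
}

# Per-subject CSV used as regressor: mean of the SD and SS measurements of
# the same pattern (symmetric in the devices; halves discretization noise).
regress_ds_on_csv <- function(delta_s, csv_tab) {
  if (nrow(csv_tab) == 0L) {
    return(tibble(pattern = character(), layer = character(), n = integer(),
                  slope = numeric(), intercept = numeric(),
                  r_squared = numeric(), p_value = numeric()))
  }
  csv_mean <- dplyr::summarise(
    dplyr::group_by(csv_tab, .data$subject_id, .data$pattern),
    csv_mm3 = mean(.data$volume_mm3), .groups = "drop"
  )
  d <- dplyr::inner_join(
    dplyr::filter(delta_s, .data$layer %in% c("deep_retina", "sattler", "haller"),
                  .data$group != "normal"),
    csv_mean, by = c("subject_id", "pattern")
  )
  dplyr::group_modify(dplyr::group_by(d, .data$pattern, .data$layer),
    function(dd, g) {
      if (nrow(dd) < 3L || sd(dd$csv_mm3) == 0) {
        return(tibble(n = nrow(dd), slope = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, p_value = NA_real_))
      }
      fit <- linear_regression(dd$csv_mm3, dd$delta)
      tibble(n = fit$n, slope = fit$slope, intercept = fit$intercept,
             r_squared = fit$r_squared, p_value = fit$p_value)
    }) |> dplyr::ungroup()
}

csv_agreement_stats <- function(csv_tab) {
  if (nrow(csv_tab) == 0L) return(list())
  wide <- tidyr::pivot_wider(
    csv_tab[, c("subject_id", "pattern", "device", "volume_mm3")],
    names_from = "device", values_from = "volume_mm3"
  )
  out <- list()
  for (pat in unique(wide$pattern)) {
    d <- wide[wide$pattern == pat & complete.cases(wide[, c("SD", "SS")]), ]
    if (nrow(d) < 2L) next
    reg <- if (sd(d$SD) > 0) linear_regression(d$SD, d$SS) else NULL
    ba <- bland_altman(d$SD, d$SS)
    out[[pat]] <- list(pattern = pat, subject_id = d$subject_id,
                       regression = reg, bland_altman = ba)
  }
  out
}

#' Flag subjects whose lesion overruns the 3 x 3 mm field of view
#'
#' A subject is flagged when its CSR mask touches the lateral boundary of the
#' small scan field (the fluid volume is then truncated); flags are
#' cross-referenced against the Bland-Altman outliers of the CSV agreement
#' analysis.
#'
#' @param report A `comparison_report`.
#' @return The report with a `fov_flags` tibble added (subject, pattern,
#'   truncation and Bland-Altman outlier status).
#' @export
flag_fov_outliers <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  csv_tab <- report$csv_measurements
  if (is.null(csv_tab) || nrow(csv_tab) == 0L) {
    report$fov_flags <- tibble(subject_id = character(), pattern = character(),
                               fov_truncated = logical(), ba_outlier = logical())
    return(report)
  }
  flags <- dplyr::summarise(
    dplyr::group_by(csv_tab, .data$subject_id, .data$pattern),
    fov_truncated = any(.data$touches_fov_boundary), .groups = "drop"
  )
  flags$ba_outlier <- FALSE
  for (pat in names(report$csv_agreement)) {
    ag <- report$csv_agreement[[pat]]
    flagged <- ag$subject_id[ag$bland_altman$outlier]
    flags$ba_outlier[flags$pattern == pat &
                       flags$subject_id %in% flagged] <- TRUE
  }
  report$fov_flags <- flags
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %d subjects, patterns %s, seed %d (config %s)\n",
    x$metadata$n_subjects, paste(x$metadata$patterns, collapse = "/"),
    x$metadata$seed, x$metadata$config_hash
  ))
  cat(sprintf("  %d signal-strength rows, %d CSV rows, %d density rows\n",
              nrow(x$signal_strength), nrow(x$csv_measurements),
              nrow(x$vessel_density)))
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$signal_strength

#' @export
glance.comparison_report <- function(x, ...) {
  tibble(n_subjects = x$metadata$n_subjects,
         seed = x$metadata$seed,
         n_fov_truncated = sum(x$fov_flags$fov_truncated),
         n_warnings = nrow(x$warnings))
}

#' @export
autoplot.comparison_report <- function(object,
                                       type = c("ds_csv", "bland_altman",
                                                "signal_strength"),
                                       pattern = "3x3mm", ...) {
  type <- match.arg(type)
  if (type == "ds_csv") {
    csv_mean <- dplyr::summarise(
      dplyr::group_by(object$csv_measurements, .data$subject_id, .data$pattern),
      csv_mm3 = mean(.data$volume_mm3), .groups = "drop"
    )
    d <- dplyr::inner_join(
      dplyr::filter(object$delta_s, .data$pattern == !!pattern,
                    .data$layer %in% c("deep_retina", "sattler", "haller")),
      csv_mean, by = c("subject_id", "pattern")
    )
    ggplot2::ggplot(d, ggplot2::aes(x = .data$csv_mm3, y = .data$delta)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4) +
      ggplot2::facet_wrap(~layer, scales = "free_y") +
      ggplot2::labs(x = "Central serous volume (mm^3)",
                    y = expression(Delta * S ~ "(SS - SD)"),
                    title = sprintf("Signal difference vs CSV, %s", pattern))
  } else if (type == "bland_altman") {
    ag <- object$csv_agreement[[pattern]]
    if (is.null(ag)) abort(sprintf("No CSV agreement analysis for %s.", pattern))
    autoplot(ag$bland_altman) +
      ggplot2::labs(title = sprintf("CSV agreement (SS - SD), %s", pattern),
                    x = "Mean CSV (mm^3)", y = "Difference (mm^3)")
  } else {
    ggplot2::ggplot(object$signal_strength,
                    ggplot2::aes(x = .data$layer, y = .data$value_rel,
                                 fill = .data$device)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_grid(group ~ pattern) +
      ggplot2::labs(x = NULL, y = "Relative layer signal strength",
                    title = "Per-layer signal strength by device")
  }
}

#' Write the report tables
#'
#' Emits the comparison report as CSV files (comma separator, header row,
#' UTF-8, `.` decimal): per-subject metrics, inter-device signal differences,
#' CSV measurements, vessel densities, the paired-test summaries, the
#' ΔS-versus-CSV regression summary, the CSV agreement summary, and the
#' field-of-view flags, plus the resolved configuration (`config.yml`).
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (nrow(report$signal_strength) == 0L) {
    abort("Report is empty; nothing to write.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(tab, name) {
    readr::write_csv(tab, file.path(dir, name))
  }
  out(report$subjects, "subjects.csv")
  out(report$signal_strength, "signal_strength.csv")
  out(report$delta_s, "delta_s.csv")
  if (nrow(report$csv_measurements) > 0L) {
    out(report$csv_measurements, "csv_measurements.csv")
  }
  out(report$vessel_density, "vessel_density.csv")
  out(report$signal_tests, "signal_tests.csv")
  out(report$density_tests, "density_tests.csv")
  out(report$ds_csv_regressions, "ds_csv_regression.csv")
  ag <- purrr::map_dfr(report$csv_agreement, function(a) {
    g <- glance(a$bland_altman)
    tibble(pattern = a$pattern,
           n = g$n,
           slope = a$regression$slope %||% NA_real_,
           intercept = a$regression$intercept %||% NA_real_,
           r_squared = a$regression$r_squared %||% NA_real_,
           p_value = a$regression$p_value %||% NA_real_,
           ba_mean_difference = g$mean_difference,
           ba_sd_difference = g$sd_difference,
           ba_lower_limit = g$lower_limit,
           ba_upper_limit = g$upper_limit,
           ba_n_outliers = g$n_outliers)
  })
  if (nrow(ag) > 0L) out(ag, "csv_agreement.csv")
  out(report$fov_flags, "fov_flags.csv")
  if (nrow(report$warnings) > 0L) out(report$warnings, "warnings.csv")
  yaml::write_yaml(report$metadata$config, file.path(dir, "config.yml"))
  invisible(dir)
}
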
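#' Per-setup system pair
#'
#' A SPECT/CT setup images the two radionuclides with the same collimator
#' and sensitivity but nuclide-specific residual scatter bias: the
#' triple-energy-window estimate misses part of the high-energy septal
#' penetration of I-131 (723/637 keV), inflating its recovered counts by
#' of order 10-20%. `setup_spec()` builds the pair of [system_model()]
#' objects for one setup.
#'
#' @param sensitivity_per_emission cps per MBq per unit emission
#'   probability (default 60, giving I-131 calibration factors near 49
#'   cps/MBq, typical of high-energy collimation).
#' @param psf_fwhm Reconstructed resolution FWHM in mm.
#' @param scatter_bias_ba133,scatter_bias_i131 Multiplicative residual
#'   count biases per nuclide (default 1 and 1.15).
#' @param background_offset_rate Additive cps per voxel.
#' @return A list with elements `ba133` and `i131`, each a
#'   [system_model()].
#' @export
setup_spec <- function(sensitivity_per_emission = 60, psf_fwhm = 20,
                       scatter_bias_ba133 = 1, scatter_bias_i131 = 1.15,
                       background_offset_rate = 0) {
  list(ba133 = system_model(sensitivity_per_emission, psf_fwhm,
                            scatter_bias_ba133, background_offset_rate),
       i131 = system_model(sensitivity_per_emission, psf_fwhm,
                           scatter_bias_i131, background_offset_rate))
}

#' Study configuration
#'
#' Everything needed to run the simulated comparison end-to-end:
#' the setups (per-system imaging models), the three source sets (two
#' solid Ba-133 sets and the liquid I-131 set), the baseplate layout, the
#' acquisition durations (30 min for cylinder scans, 60 min for the
#' uniform-phantom calibration scan), and the voxel grid.
#'
#' @param setups Named list of [setup_spec()] pairs.
#' @param scan_time Acquisition time (`POSIXct`); solid-source activities
#'   are decay-corrected from their assay reference to this time.
#' @param stock_concentration_MBq_mL I-131 stock activity concentration at
#'   scan time (study median 0.18 MBq/mL).
#' @param stock_concentration_u_rel Relative standard uncertainty of the
#'   concentration.
#' @param icf_activity_MBq I-131 activity in the uniformly filled Jaszczak
#'   phantom (study median 39.9 MBq).
#' @param icf_activity_u_rel Its relative standard uncertainty.
#' @param layout A [phantom_layout()], or `NULL` to optimise one with
#'   [optimize_placement()] (coarser 2 mm / 10 degree grid for speed).
#' @param voxel_size,supersample,padding Grid parameters for
#'   [voxelize_layout()].
#' @param duration_cylinder_s,duration_icf_s Acquisition durations (s).
#' @param enlarged_margin_mm Margin of the enlarged calibration VOI, or
#'   `NULL` for twice the setup's PSF FWHM.
#' @param seed Base integer seed; every simulated scan derives its own
#'   sub-seed deterministically from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(setups,
                         scan_time = as.POSIXct("2019-06-15 12:00:00",
                                                tz = "UTC"),
                         stock_concentration_MBq_mL = 0.18,
                         stock_concentration_u_rel = 0.01,
                         icf_activity_MBq = 39.9,
                         icf_activity_u_rel = 0.01,
                         layout = NULL,
                         voxel_size = 4.42, supersample = 2L, padding = 30,
                         duration_cylinder_s = 1800,
                         duration_icf_s = 3600,
                         enlarged_margin_mm = NULL,
                         seed = 1L) {
  stopifnot(length(setups) >= 1L, !is.null(names(setups)),
            duration_cylinder_s > 0, duration_icf_s > 0)
  structure(
    list(setups = setups, scan_time = scan_time,
         stock_concentration_MBq_mL = stock_concentration_MBq_mL,
         stock_concentration_u_rel = stock_concentration_u_rel,
         icf_activity_MBq = icf_activity_MBq,
         icf_activity_u_rel = icf_activity_u_rel,
         layout = layout, voxel_size = voxel_size,
         supersample = as.integer(supersample), padding = padding,
         duration_cylinder_s = duration_cylinder_s,
         duration_icf_s = duration_icf_s,
         enlarged_margin_mm = enlarged_margin_mm,
         seed = as.integer(seed)),
    class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the arguments of [study_config()] and [setup_spec()]:
#' a `setups` mapping of name to `sensitivity_per_emission`, `psf_fwhm`,
#' `scatter_bias_ba133`, `scatter_bias_i131`, `background_offset_rate`;
#' an optional `layout` with `positions` (list of id/x/y) and envelope
#' fields; and any of the scalar options.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$setups)) stop("config must define setups")
  setups <- lapply(y$setups, function(s) do.call(setup_spec, s))
  layout <- NULL
  if (!is.null(y$layout)) {
    pos <- do.call(rbind, lapply(y$layout$positions, as.data.frame))
    args <- y$layout[setdiff(names(y$layout), "positions")]
    layout <- do.call(phantom_layout, c(list(positions = pos), args))
  }
  scalars <- y[setdiff(names(y), c("setups", "layout"))]
  if (!is.null(scalars$scan_time))
    scalars$scan_time <- as.POSIXct(scalars$scan_time, tz = "UTC")
  do.call(study_config, c(list(setups = setups, layout = layout), scalars))
}

# Activity-concentration volume for the uniformly filled Jaszczak phantom.
uniform_phantom_volume <- function(activity_MBq, jaszczak_diameter = 216,
                                   jaszczak_height = 186, voxel_size = 4.42,
                                   supersample = 2L, padding = 30) {
  jasz <- cylinder_spec("JASZ", diameter = jaszczak_diameter,
                        height = jaszczak_height,
                        activity_kBq = activity_MBq * 1000)
  lay <- phantom_layout(data.frame(id = "JASZ", x = 0, y = 0),
                        jaszczak_diameter = jaszczak_diameter,
                        jaszczak_height = jaszczak_height, wall_margin = 0)
  voxelize_layout(lay, list(JASZ = jasz), voxel_size = voxel_size,
                  supersample = supersample, padding = padding)
}

# Deterministic per-scan seed derived from the base seed.
scan_seed <- function(seed, setup_idx, scan_idx) {
  (seed + 97L * setup_idx + 7L * scan_idx) %% 2147483647L
}

# Pseudo-ICFs for the four cylinders of one simulated scan.
measure_cylinder_scan <- function(image, layout, cylinders,
                                  activities_MBq, activity_u_rel,
                                  use_active_volume = TRUE) {
  pos <- layout$positions
  fwhm <- image$truth$system$psf_fwhm
  out <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    cyl <- cylinders[[pos$id[i]]]
    target <- if (use_active_volume) cyl$active_volume else cyl$nominal_volume
    half <- cyl$diameter / 2 + fwhm
    region <- array(FALSE, dim = dim(image$counts))
    ix <- abs(image$xs - pos$x[i]) <= half
    iy <- abs(image$ys - pos$y[i]) <= half
    region[ix, iy, ] <- TRUE
    voi <- threshold_matched_voi(image, target, region = region)
    out[[i]] <- icf(voi_counts(image, voi), image$duration_s,
                    activities_MBq[[cyl$id]],
                    activity_u_rel = activity_u_rel[[cyl$id]],
                    kind = "pseudo_ICF", cylinder = cyl$id)
  }
  names(out) <- pos$id
  out
}

#' Run the full simulated comparison study
#'
#' For every setup in the configuration this simulates the four scans of
#' the protocol (the two solid Ba-133 source sets, the liquid I-131
#' cylinders, and the uniformly filled I-131 Jaszczak phantom), delineates
#' the volume-matched and enlarged VOIs, computes pseudo-ICFs and the ICF
#' with their uncertainty budgets, combines the dual-source Ba-133
#' measurements, fits the setup-specific cross-calibration line, compares
#' it with the emission-probability-ratio method, and fits the four
#' pseudo-recovery curves. The dual-source equivalence test (Wilcoxon
#' signed rank across all setup/cylinder pairs) is run at study level.
#'
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, result tables are
#'   written as CSV with stable column order, plus a JSON manifest with
#'   file checksums.
#' @return An object of class `study_report`: data frames `pseudo_icf`,
#'   `crosscal`, `relative_change`, `recovery`, the `wilcoxon` test, the
#'   per-setup detail list `setups`, and the `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  nuc_ba <- ba133(); nuc_i <- i131()
  epr <- emission_probability_ratio(nuc_ba, nuc_i)
  sets <- list(CEA = ba133_source_set("CEA"), CMI = ba133_source_set("CMI"))
  i_set <- i131_cylinder_set(config$stock_concentration_MBq_mL,
                             config$stock_concentration_u_rel,
                             reference_time = config$scan_time)
  geometry <- i131_cylinder_set(1)  # unit-concentration geometry carrier
  layout <- config$layout
  if (is.null(layout)) {
    fwhm_max <- max(vapply(config$setups, function(s) s$ba133$psf_fwhm, 0))
    layout <- optimize_placement(geometry, psf_fwhm = fwhm_max,
                                 radius_step = 2, angle_step = 10)
  }
  validate_phantom_layout(layout, geometry)
  ids <- layout$positions$id

  # decay-correct the solid sources to scan time; activities in MBq
  ba_act <- lapply(sets, function(set) {
    vapply(set[ids], function(cyl) {
      a <- cyl$activity_kBq / 1000
      if (!is.null(cyl$reference_time) && !is.null(config$scan_time))
        a <- decay_correct(a, nuc_ba, from = cyl$reference_time,
                           to = config$scan_time)
      a
    }, 0)
  })
  ba_u_rel <- lapply(sets, function(set)
    vapply(set[ids], function(cyl) cyl$activity_u_kBq / cyl$activity_kBq, 0))
  i_act <- vapply(i_set[ids], function(cyl) cyl$activity_kBq / 1000, 0)
  i_u_rel <- vapply(i_set[ids],
                    function(cyl) cyl$activity_u_kBq / cyl$activity_kBq, 0)

  # activity volumes are layout x activities; reuse across setups
  av <- list(
    CEA = voxelize_layout(layout, sets$CEA, config$voxel_size,
                          config$supersample, config$padding,
                          activities_MBq = ba_act$CEA),
    CMI = voxelize_layout(layout, sets$CMI, config$voxel_size,
                          config$supersample, config$padding,
                          activities_MBq = ba_act$CMI),
    I = voxelize_layout(layout, i_set, config$voxel_size,
                        config$supersample, config$padding),
    JASZ = uniform_phantom_volume(config$icf_activity_MBq,
                                  layout$jaszczak_diameter,
                                  layout$jaszczak_height,
                                  config$voxel_size, config$supersample,
                                  config$padding))
  jasz_cyl <- cylinder_spec("JASZ", layout$jaszczak_diameter,
                            layout$jaszczak_height)

  pseudo_rows <- list(); cc_rows <- list(); chg_rows <- list()
  rec_rows <- list(); details <- list()
  volumes <- vapply(i_set[ids], function(cyl) cyl$nominal_volume, 0)

  for (si in seq_along(config$setups)) {
    sname <- names(config$setups)[si]
    setup <- config$setups[[si]]
    margin <- if (is.null(config$enlarged_margin_mm))
      2 * setup$i131$psf_fwhm else config$enlarged_margin_mm

    img <- list(
      CEA = simulate_count_image(av$CEA, setup$ba133, nuc_ba,
                                 config$duration_cylinder_s,
                                 seed = scan_seed(config$seed, si, 1L)),
      CMI = simulate_count_image(av$CMI, setup$ba133, nuc_ba,
                                 config$duration_cylinder_s,
                                 seed = scan_seed(config$seed, si, 2L)),
      I = simulate_count_image(av$I, setup$i131, nuc_i,
                               config$duration_cylinder_s,
                               seed = scan_seed(config$seed, si, 3L)),
      JASZ = simulate_count_image(av$JASZ, setup$i131, nuc_i,
                                  config$duration_icf_s,
                                  seed = scan_seed(config$seed, si, 4L)))

    res <- list(
      CEA = measure_cylinder_scan(img$CEA, layout, sets$CEA,
                                  ba_act$CEA, ba_u_rel$CEA),
      CMI = measure_cylinder_scan(img$CMI, layout, sets$CMI,
                                  ba_act$CMI, ba_u_rel$CMI),
      I = measure_cylinder_scan(img$I, layout, i_set, i_act, i_u_rel,
                                use_active_volume = FALSE))
    combined <- lapply(ids, function(id)
      combine_dual_source(res$CEA[[id]], res$CMI[[id]]))
    names(combined) <- ids

    base <- nominal_geometry_voi(img$JASZ, jasz_cyl)
    big <- enlarged_voi(img$JASZ, base, margin)
    icf_jasz <- icf(voi_counts(img$JASZ, big), img$JASZ$duration_s,
                    config$icf_activity_MBq,
                    activity_u_rel = config$icf_activity_u_rel,
                    kind = "ICF")

    for (id in ids) {
      for (set in c("CEA", "CMI", "I")) {
        r <- res[[set]][[id]]
        pseudo_rows[[length(pseudo_rows) + 1L]] <- data.frame(
          setup = sname, source = set,
          nuclide = if (set == "I") "I-131" else "Ba-133",
          cylinder = id, value = r$value, u_k1 = r$u, u_k2 = 2 * r$u)
      }
      cmb <- combined[[id]]
      pseudo_rows[[length(pseudo_rows) + 1L]] <- data.frame(
        setup = sname, source = "combined", nuclide = "Ba-133",
        cylinder = id, value = cmb$mean, u_k1 = cmb$u, u_k2 = 2 * cmb$u)
    }
    pseudo_rows[[length(pseudo_rows) + 1L]] <- data.frame(
      setup = sname, source = "I", nuclide = "I-131", cylinder = "JASZ",
      value = icf_jasz$value, u_k1 = icf_jasz$u, u_k2 = 2 * icf_jasz$u)

    pairs <- data.frame(
      cylinder = ids,
      i131 = vapply(ids, function(id) res$I[[id]]$value, 0),
      ba133 = vapply(ids, function(id) combined[[id]]$mean, 0),
      u_i131 = vapply(ids, function(id) res$I[[id]]$u, 0),
      u_ba133 = vapply(ids, function(id) combined[[id]]$u, 0))
    fit <- fit_cross_calibration(pairs)
    cc_rows[[length(cc_rows) + 1L]] <- data.frame(
      setup = sname, offset = fit$offset, offset_se = fit$offset_se,
      slope = fit$slope, slope_se = fit$slope_se, n = fit$n,
      emission_ratio = epr$ratio)

    pred_ratio <- apply_cross_calibration(pairs$ba133, epr)
    pred_line <- apply_cross_calibration(pairs$ba133, fit)
    chg_ratio <- relative_percent_change(pairs$i131, pred_ratio)
    chg_line <- relative_percent_change(pairs$i131, pred_line)
    chg_rows[[length(chg_rows) + 1L]] <- data.frame(
      setup = sname, cylinder = ids,
      change_ratio_pct = chg_ratio, change_line_pct = chg_line)

    fits <- list(
      i131 = fit_recovery_curve(volumes, pairs$i131),
      ba133 = fit_recovery_curve(volumes, pairs$ba133),
      ba133_ratio_cc = fit_recovery_curve(volumes, pred_ratio),
      ba133_line_cc = fit_recovery_curve(volumes, pred_line))
    for (fn in names(fits)) {
      f <- fits[[fn]]
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        setup = sname, curve = fn, plateau = f$plateau, v0 = f$v0,
        b = f$b, sse = f$sse)
    }

    details[[sname]] <- list(images = NULL, pseudo_icf = res,
                             combined = combined, icf = icf_jasz,
                             crosscal = fit, recovery = fits,
                             pairs = pairs,
                             median_abs_change = c(
                               ratio = stats::median(abs(chg_ratio)),
                               line = stats::median(abs(chg_line))))
  }

  pseudo_icf <- do.call(rbind, pseudo_rows)
  cea <- pseudo_icf[pseudo_icf$source == "CEA", ]
  cmi <- pseudo_icf[pseudo_icf$source == "CMI", ]
  wil <- if (nrow(cea) >= 5L)
    tryCatch(wilcoxon_signed_rank(cea$value, cmi$value),
             error = function(e) NULL) else NULL

  report <- structure(
    list(pseudo_icf = pseudo_icf,
         crosscal = do.call(rbind, cc_rows),
         relative_change = do.call(rbind, chg_rows),
         recovery = do.call(rbind, rec_rows),
         wilcoxon = wil, setups = details, layout = layout,
         emission_ratio = epr, config = config, manifest = NULL),
    class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(pseudo_icf = "pseudo_icf.csv", crosscal = "crosscal_fits.csv",
               relative_change = "relative_change.csv",
               recovery = "recovery_fits.csv")
    for (nm in names(files)) {
      utils::write.csv(report[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(serialize_config(config), cfg_file)
    paths <- file.path(out_dir, c(files, "config.yaml"))
    manifest <- list(
      package = "spectcal",
      version = as.character(utils::packageVersion("spectcal")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = unname(tools::md5sum(cfg_file)),
      files = data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    report$manifest <- manifest
  }
  report
}

# Plain-list view of a config for hashing / YAML round trips.
serialize_config <- function(config) {
  list(
    setups = lapply(config$setups, function(s) list(
      sensitivity_per_emission = s$ba133$sensitivity_per_emission,
      psf_fwhm = s$ba133$psf_fwhm,
      scatter_bias_ba133 = s$ba133$scatter_bias,
      scatter_bias_i131 = s$i131$scatter_bias,
      background_offset_rate = s$ba133$background_offset_rate)),
    scan_time = format(config$scan_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    stock_concentration_MBq_mL = config$stock_concentration_MBq_mL,
    stock_concentration_u_rel = config$stock_concentration_u_rel,
    icf_activity_MBq = config$icf_activity_MBq,
    icf_activity_u_rel = config$icf_activity_u_rel,
    voxel_size = config$voxel_size, supersample = config$supersample,
    padding = config$padding,
    duration_cylinder_s = config$duration_cylinder_s,
    duration_icf_s = config$duration_icf_s,
    seed = config$seed)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  setups: %s\n", paste(names(x$setups), collapse = ", ")))
  cat(sprintf("  emission-probability ratio: %.3f +/- %.3f\n",
              x$emission_ratio$ratio, x$emission_ratio$u))
  cat("  cross-calibration fits:\n")
  print(x$crosscal, row.names = FALSE)
  for (s in names(x$setups)) {
    m <- x$setups[[s]]$median_abs_change
    cat(sprintf("  %s median |change|: ratio %.2f%%, line %.2f%%\n",
                s, m["ratio"], m["line"]))
  }
  if (!is.null(x$wilcoxon))
    cat(sprintf("  dual-source Wilcoxon: V = %g, p = %.3g (n = %d)\n",
                x$wilcoxon$statistic, x$wilcoxon$p.value, x$wilcoxon$n))
  invisible(x)
}
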
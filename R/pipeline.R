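#' Configuration of an end-to-end analysis run
#'
#' Collects every tunable of the pipeline with the study defaults:
#' 0.2/0.5/1/2 Hz staircase of 120 s intervals, 30 s analysis window,
#' 1.5-2.5 um sarcomere band, 1.05 um dichotomization threshold and
#' 5 x 0.25 mm slice cross-section.  With no input manifests the run is
#' fully synthetic, drawing every modality from the generators.
#'
#' @param rng_seed integer seed governing all synthetic inputs.
#' @param n_samples cohort size for the synthetic run.
#' @param n_imaging_phantoms number of t-system phantoms imaged.
#' @param n_trace_samples number of samples for which a force trace is
#'   generated and analyzed.
#' @param run_imaging,run_morphometry,run_kinetics,run_stats stage
#'   switches; a disabled stage is marked absent in the report.
#' @param imaging,morphometry,kinetics,stats named lists of stage
#'   parameters overriding the defaults below.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rng_seed = 1L,
                       n_samples = 13L,
                       n_imaging_phantoms = 2L,
                       n_trace_samples = 2L,
                       run_imaging = TRUE, run_morphometry = TRUE,
                       run_kinetics = TRUE, run_stats = TRUE,
                       imaging = list(), morphometry = list(),
                       kinetics = list(), stats = list(),
                       output_dir = NULL) {
  imaging_defaults <- list(
    cell_extent_um = c(5.8, 5.8, 5.8), voxel_size_um = c(0.1, 0.1, 0.1),
    geometry = "full-lattice", spacings_um = c(1.0, 1.6),
    tubule_radius_um = 0.15,
    noise_sd = 2, attenuation_coefficient_per_um = 0.01,
    blur_sigma_um = 0.1, psf_sigma_um = 0.1, surface_margin_um = 0.3,
    rl_iterations = 10L)
  morphometry_defaults <- list(
    n_cells = 100L, disarray_fraction = 0.1, angle_sd_deg = 10,
    pixel_size_um = 0.5, sarcomere_length_um = 2.05,
    sarcomere_pixel_um = 0.15, band_um = c(1.5, 2.5))
  kinetics_defaults <- list(
    protocol = default_protocol(), window_s = 30,
    geometry = slice_geometry(), noise_sd = 0.002, sampling_hz = 1000)
  stats_defaults <- list(threshold_um = 1.05)
  structure(list(
    rng_seed = as.integer(rng_seed), n_samples = n_samples,
    n_imaging_phantoms = n_imaging_phantoms,
    n_trace_samples = n_trace_samples,
    run_imaging = run_imaging, run_morphometry = run_morphometry,
    run_kinetics = run_kinetics, run_stats = run_stats,
    imaging = utils::modifyList(imaging_defaults, imaging),
    morphometry = utils::modifyList(morphometry_defaults, morphometry),
    kinetics = utils::modifyList(kinetics_defaults, kinetics),
    stats = utils::modifyList(stats_defaults, stats),
    output_dir = output_dir),
    class = "run_config")
}

#' Run the full synthetic structure-function pipeline
#'
#' Executes, per the configuration: (1) imaging -- t-system phantoms are
#' generated, pushed through attenuation correction, deconvolution,
#' segmentation and the distance metric, and compared with their ground
#' truth; (2) morphometry -- watershed segmentation, orientation
#' statistics and sarcomere length on a generated mosaic and striation
#' pattern; (3) kinetics -- per-frequency twitch parameters and FFR
#' ratios extracted from generated staircase traces; (4) statistics --
#' the univariate fits, the no-intercept interaction model with its
#' likelihood-ratio test against the dTT-only model, and the
#' dichotomized per-frequency group comparison, all on the synthetic
#' cohort.  Identical configuration and seed give identical reports.
#'
#' @param config a [run_config()].
#' @return An object of class `analysis_report`; stages that are disabled
#'   or fail are recorded under `$gaps`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(provenance = list(
    rng_seed = config$rng_seed,
    package_version = as.character(utils::packageVersion("myoslice")),
    timestamp = NA_character_))
  gaps <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      gaps <<- c(gaps, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  cohort <- gen_cohort(n_samples = config$n_samples,
                       rng_seed = config$rng_seed)
  report$samples <- cohort$samples
  report$generating_truth <- cohort$truth

  if (config$run_imaging) {
    report$imaging <- run_stage("imaging", {
      im <- config$imaging
      spacings <- rep(im$spacings_um,
                      length.out = config$n_imaging_phantoms)
      rows <- lapply(seq_len(config$n_imaging_phantoms), function(i) {
        spec <- tubule_phantom_spec(
          cell_extent_um = im$cell_extent_um,
          voxel_size_um = im$voxel_size_um, geometry = im$geometry,
          lattice_spacing_um = spacings[i],
          tubule_radius_um = im$tubule_radius_um,
          noise_sd = im$noise_sd,
          attenuation_coefficient_per_um =
            im$attenuation_coefficient_per_um,
          blur_sigma_um = im$blur_sigma_um,
          rng_seed = config$rng_seed + i)
        ph <- gen_tsystem_stack(spec)
        metrics <- analyze_tsystem_stack(
          ph$stack, psf_sigma_um = im$psf_sigma_um,
          iterations = im$rl_iterations,
          surface_margin_um = im$surface_margin_um)
        data.frame(stack_id = i, spacing_um = spacings[i],
                   delta_tt_um = metrics$delta_tt_um,
                   true_delta_tt_um = ph$truth$true_delta_tt_um)
      })
      do.call(rbind, rows)
    })
  } else gaps <- c(gaps, "imaging: disabled")

  if (config$run_morphometry) {
    report$morphometry <- run_stage("morphometry", {
      mo <- config$morphometry
      mosaic <- gen_myocyte_mosaic(
        n_cells = mo$n_cells, disarray_fraction = mo$disarray_fraction,
        angle_sd_deg = mo$angle_sd_deg, pixel_size_um = mo$pixel_size_um,
        rng_seed = config$rng_seed)
      lmap <- watershed_segment(mosaic$image, mo$pixel_size_um)
      ori <- segment_orientation(lmap)
      stats <- orientation_stats(ori$orientation_deg)
      sl_img <- gen_sarcomere_pattern(
        length_um = mo$sarcomere_length_um,
        pixel_size_um = mo$sarcomere_pixel_um,
        rng_seed = config$rng_seed)
      sl <- sarcomere_length(sl_img, mo$sarcomere_pixel_um,
                             band_um = mo$band_um)
      list(n_cells_found = nrow(lmap$cells),
           n_cells_true = mo$n_cells,
           main_orientation_deg = stats$main_orientation_deg,
           dispersion_deg = stats$dispersion_deg,
           disarray_fraction = stats$disarray_fraction,
           true_disarray_fraction = mosaic$truth$disarray_fraction,
           sarcomere_length_um = as.numeric(sl),
           true_sarcomere_length_um = mo$sarcomere_length_um)
    })
  } else gaps <- c(gaps, "morphometry: disabled")

  if (config$run_kinetics) {
    report$kinetics <- run_stage("kinetics", {
      ki <- config$kinetics
      idx <- seq_len(min(config$n_trace_samples, config$n_samples))
      rows <- lapply(idx, function(i) {
        s <- cohort$samples[i, ]
        amps <- c(`0.2` = 0.9, `0.5` = 1,
                  `1` = s$ffr_1_0p5, `2` = s$ffr_2_0p5)
        gen <- gen_force_trace(protocol = ki$protocol,
                               amplitude_mN = amps,
                               noise_sd = ki$noise_sd,
                               sampling_hz = ki$sampling_hz,
                               rng_seed = config$rng_seed + 100L + i)
        fr <- interval_average(gen$trace, window_s = ki$window_s,
                               geometry = ki$geometry)
        ratios <- ffr_ratios(fr)
        data.frame(sample_id = s$sample_id,
                   ffr_1_0p5 = ratios$ffr_1_0p5,
                   ffr_2_0p5 = ratios$ffr_2_0p5,
                   programmed_ffr_1_0p5 = gen$truth$ffr_1_0p5,
                   programmed_ffr_2_0p5 = gen$truth$ffr_2_0p5,
                   ttp_1hz_s = fr$table$ttp_s[fr$table$frequency_hz == 1],
                   ttr_1hz_s = fr$table$ttr_s[fr$table$frequency_hz == 1])
      })
      do.call(rbind, rows)
    })
  } else gaps <- c(gaps, "kinetics: disabled")

  if (config$run_stats) {
    report$fits <- run_stage("stats", {
      s <- report$samples
      fit_ffr1 <- linear_fit(s$delta_tt_um, s$ffr_1_0p5)
      fit_ffr2 <- linear_fit(s$delta_tt_um, s$ffr_2_0p5)
      fit_ttr <- linear_fit(s$delta_tt_um, s$ttr_s)
      fit_cd90_serca <- linear_fit(s$serca2_plb, s$cd90_s)
      full <- interaction_fit(s$delta_tt_um, s$ncx1, s$ttr_s)
      reduced <- interaction_fit(s$delta_tt_um, rep(0, nrow(s)), s$ttr_s)
      lrt <- likelihood_ratio_test(full, reduced)
      list(ffr1_vs_dtt = fit_ffr1, ffr2_vs_dtt = fit_ffr2,
           ttr_vs_dtt = fit_ttr, cd90_vs_serca2_plb = fit_cd90_serca,
           interaction = full, interaction_vs_dtt_only = lrt)
    })
    report$group_comparison <- run_stage("group comparison", {
      frequency_group_comparison(report$samples,
                                 threshold_um = config$stats$threshold_um)
    })
  } else gaps <- c(gaps, "stats: disabled")

  report$gaps <- gaps
  report <- structure(report, class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (seed", x$provenance$rng_seed, ")\n")
  cat(" samples:", nrow(x$samples), "\n")
  if (!is.null(x$imaging))
    cat(sprintf(" imaging: %d stacks, mean |dTT error| %.3g um\n",
                nrow(x$imaging),
                mean(abs(x$imaging$delta_tt_um -
                         x$imaging$true_delta_tt_um))))
  if (!is.null(x$morphometry))
    cat(sprintf(" morphometry: %d cells, disarray %.2f, sarcomere %.3f um\n",
                x$morphometry$n_cells_found,
                x$morphometry$disarray_fraction,
                x$morphometry$sarcomere_length_um))
  if (!is.null(x$fits))
    cat(sprintf(" interaction model: b1 = %.3f, ratio = %.3f (LRT p = %.3g)\n",
                x$fits$interaction$b1,
                x$fits$interaction$interaction_ratio,
                x$fits$interaction_vs_dtt_only$p_value))
  if (length(x$gaps)) cat(" gaps:", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

# Serialize the report tables as CSV plus a JSON summary.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$samples, file.path(dir, "samples.csv"))
  if (!is.null(report$imaging))
    write_table(report$imaging, file.path(dir, "imaging.csv"))
  if (!is.null(report$kinetics))
    write_table(report$kinetics, file.path(dir, "kinetics.csv"))
  if (!is.null(report$group_comparison))
    write_table(report$group_comparison,
                file.path(dir, "group_comparison.csv"))
  summary <- list(provenance = report$provenance,
                  morphometry = report$morphometry,
                  gaps = report$gaps)
  if (!is.null(report$fits))
    summary$fits <- list(
      ffr1_vs_dtt = report$fits$ffr1_vs_dtt[c("r2", "p_value")],
      interaction = report$fits$interaction[c("b1", "b2",
                                              "interaction_ratio", "r2")],
      lrt_p = report$fits$interaction_vs_dtt_only$p_value)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
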
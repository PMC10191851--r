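# Configuration handling and the end-to-end demo pipeline: simulate all
# input classes, then run the ECoG, decoding, connectivity, spectral, MEA and
# statistics stages in dependency order, logging every parameter used.

default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "ecog", "decode", "connect", "spectra", "mea",
               "stats"),
    ecog = list(n_participants = 4, n_channels = 8,
                fraction_tumour_channels = 0.5, fs = 1200,
                n_trials_per_condition = 8, tumour_amplitude_ratio = 2,
                condition_effect_size = 2, noise_sd = 1,
                kurtosis_max = 5.0, max_latency_s = 2.0,
                hgp_band = c(70, 110), fir_order = 300,
                task_window_s = c(0, 1)),
    decoding = list(window_s = c(-0.5, 0.5), cost = 1),
    connectivity = list(n_voxels_per_hemisphere = 60, fs = 200, duration = 60,
                        alpha_freq = 10, base_coupling = 0.25,
                        n_lesion_voxels = 10, lesion_coupling_boost = 3,
                        band = c(8, 12), segment_s = 1, overlap = 0.5),
    spectra = list(offset_b = 1, knee_k = 10, exponent_chi = 2,
                   peak_centre_hz = 40, peak_height_log10 = 0.3,
                   peak_width_hz = 4, noise_sd_log = 0.02,
                   gamma_band = c(30, 50)),
    mea = list(n_wells = 2, n_electrodes_per_well = 16, duration = 300,
               background_rate = 0.2, n_network_bursts = 10,
               burst_electrode_fraction = 0.5, burst_n_spikes = 80,
               auncc_bin_s = 0.005, auncc_max_lag_s = 0.010),
    stats = list(cohort_n_per_group = 120,
                 cohort_medians_weeks = c(71, 123),
                 censoring_fraction = 0.2)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

check_config_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      check_config_keys(as.list(cfg[[nm]]), ref[[nm]], paste0(path, nm, "."))
    }
  }
}

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, validates every key against the
#' package defaults (unknown keys are rejected) and fills unset values with
#' the defaults. `NULL` returns the default configuration.
#'
#' @param path YAML/JSON config path, or NULL.
#' @return a complete configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    check_config_keys(user, cfg)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Run the end-to-end demo pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> ecog -> decode | connect | spectra | mea | stats), writing a
#' JSON report plus CSV/NIfTI products into `out_dir`. Identical config and
#' seed give byte-identical outputs.
#'
#' @param config a configuration list from [load_config()], or a path.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) load_config(config) else
    merge_config(default_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- seed
  valid <- c("simulate", "ecog", "decode", "connect", "spectra", "mea", "stats")
  bad <- setdiff(cfg$stages, valid)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(valid, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg)
  seeds <- split_seeds(cfg$seed, 5)

  needs_sim <- any(c("ecog", "decode", "connect", "spectra", "mea", "stats")
                   %in% cfg$stages)
  sim <- NULL
  if ("simulate" %in% cfg$stages || needs_sim) {
    ec <- cfg$ecog
    sim <- list(
      ecog = generate_ecog_dataset(ecog_sim_spec(
        n_participants = ec$n_participants, n_channels = ec$n_channels,
        fraction_tumour_channels = ec$fraction_tumour_channels, fs = ec$fs,
        n_trials_per_condition = ec$n_trials_per_condition,
        tumour_amplitude_ratio = ec$tumour_amplitude_ratio,
        condition_effect_size = ec$condition_effect_size,
        noise_sd = ec$noise_sd, seed = seeds[1])),
      voxels = generate_voxel_dataset(voxel_sim_spec(
        n_voxels_per_hemisphere = cfg$connectivity$n_voxels_per_hemisphere,
        fs = cfg$connectivity$fs, duration = cfg$connectivity$duration,
        alpha_freq = cfg$connectivity$alpha_freq,
        base_coupling = cfg$connectivity$base_coupling,
        lesion_voxel_ids = seq_len(cfg$connectivity$n_lesion_voxels),
        lesion_coupling_boost = cfg$connectivity$lesion_coupling_boost,
        seed = seeds[2])),
      spectrum = generate_spectrum(spectrum_sim_spec(
        offset_b = cfg$spectra$offset_b, knee_k = cfg$spectra$knee_k,
        exponent_chi = cfg$spectra$exponent_chi,
        peaks = data.frame(centre_hz = cfg$spectra$peak_centre_hz,
                           height_log10 = cfg$spectra$peak_height_log10,
                           width_hz = cfg$spectra$peak_width_hz),
        noise_sd_log = cfg$spectra$noise_sd_log, seed = seeds[3])),
      mea = generate_spike_data(raster_sim_spec(
        n_wells = cfg$mea$n_wells,
        n_electrodes_per_well = cfg$mea$n_electrodes_per_well,
        duration = cfg$mea$duration,
        background_rate = cfg$mea$background_rate,
        network_burst_schedule = regular_burst_schedule(
          cfg$mea$n_network_bursts, cfg$mea$duration,
          cfg$mea$burst_electrode_fraction, cfg$mea$burst_n_spikes),
        seed = seeds[4])),
      cohort = generate_cohort(cohort_sim_spec(
        n_per_group = cfg$stats$cohort_n_per_group,
        median_survival_per_group = cfg$stats$cohort_medians_weeks,
        censoring_fraction = cfg$stats$censoring_fraction,
        seed = seeds[5]))
    )
    report$simulate <- list(done = TRUE, seeds = as.integer(seeds))
  }

  hgp_table <- NULL
  ersp_list <- NULL
  if (any(c("ecog", "decode", "stats") %in% cfg$stages)) {
    if (is.null(sim)) stop("missing upstream product: simulate")
    ec <- cfg$ecog
    rows <- list()
    ersp_list <- list()
    for (p in seq_along(sim$ecog$participants)) {
      part <- sim$ecog$participants[[p]]
      scr <- reject_noisy_channels(part$recording, ec$kurtosis_max)
      sel <- select_trials(part$trials, ec$max_latency_s)
      ep <- epoch_speech_locked(scr$recording, sel)
      hgp <- compute_hgp(ep, band = ec$hgp_band, fir_order = ec$fir_order)
      cm <- hgp_channel_means(hgp, window_s = ec$task_window_s)
      cm$participant <- sprintf("P%02d", p)
      rows[[p]] <- cm
      if ("decode" %in% cfg$stages) {
        ersp <- compute_ersp(scr$recording, sel)
        ersp_list[[p]] <- ersp_features(ersp, sprintf("P%02d", p),
                                        cfg$decoding$window_s)
      }
    }
    hgp_table <- do.call(rbind, rows)
    names(hgp_table)[names(hgp_table) == "hgp_mean"] <- "hgp"
    write.csv(hgp_table, file.path(out_dir, "hgp_channel_means.csv"),
              row.names = FALSE)
    report$ecog <- list(n_channels_analysed = nrow(hgp_table),
                        band = ec$hgp_band, fir_order = ec$fir_order)
  }

  if ("decode" %in% cfg$stages) {
    features <- do.call(rbind, ersp_list)
    dec <- decode_lopo(features, cost = cfg$decoding$cost)
    write.csv(data.frame(participant = names(dec$per_fold_accuracy),
                         accuracy = dec$per_fold_accuracy),
              file.path(out_dir, "decode_folds.csv"), row.names = FALSE)
    report$decode <- list(mean_accuracy = dec$mean_accuracy,
                          n_test_trials = dec$n_test_trials,
                          p_value = dec$p_value, cost = cfg$decoding$cost,
                          window_s = cfg$decoding$window_s)
  }

  if ("connect" %in% cfg$stages) {
    if (is.null(sim)) stop("missing upstream product: simulate")
    cmap <- connectivity_map(sim$voxels, band = cfg$connectivity$band,
                             segment_s = cfg$connectivity$segment_s,
                             overlap = cfg$connectivity$overlap)
    files <- write_connectivity_nifti(cmap, file.path(out_dir, "connectivity"))
    hfc <- count_hfc_in_tumour(cmap$map$conn_class, sim$voxels$tumour_mask)
    report$connect <- list(
      n_voxels = nrow(cmap$map),
      n_hfc = sum(cmap$map$conn_class == "HFC"),
      hfc_voxel_count_in_tumour = hfc$hfc_voxel_count,
      hfc_positive = hfc$hfc_positive,
      band = cfg$connectivity$band)
  }

  if ("spectra" %in% cfg$stages) {
    if (is.null(sim)) stop("missing upstream product: simulate")
    fit <- fit_aperiodic(sim$spectrum)
    gp <- gamma_power(sim$spectrum, fit, band = cfg$spectra$gamma_band)
    write.csv(data.frame(freq_hz = sim$spectrum$freqs,
                         psd = sim$spectrum$psd,
                         aperiodic_log10 = aperiodic_curve(fit,
                                                           sim$spectrum$freqs)),
              file.path(out_dir, "spectrum_fit.csv"), row.names = FALSE)
    report$spectra <- list(offset_b = fit$offset_b, knee_k = fit$knee_k,
                           exponent_chi = fit$exponent_chi,
                           gamma_power = gp,
                           gamma_band = cfg$spectra$gamma_band)
  }

  if ("mea" %in% cfg$stages) {
    if (is.null(sim)) stop("missing upstream product: simulate")
    write_spike_csv(sim$mea$spikes, file.path(out_dir, "spikes.csv"))
    well_rows <- lapply(names(sim$mea$spikes$spikes), function(w) {
      trains <- sim$mea$spikes$spikes[[w]]
      met <- summarize_firing(trains, duration = cfg$mea$duration)
      nb <- detect_network_bursts(trains, met$active)
      met <- summarize_firing(trains, duration = cfg$mea$duration,
                              network_bursts = nb)
      au <- compute_auncc(trains[met$active], cfg$mea$duration,
                          bin_s = cfg$mea$auncc_bin_s,
                          max_lag_s = cfg$mea$auncc_max_lag_s)
      data.frame(well = w, n_active = sum(met$active), wmfr_hz = met$wmfr,
                 n_network_bursts = nrow(nb),
                 network_burst_freq_hz = met$network_burst_freq,
                 auncc = au$auncc)
    })
    well_metrics <- do.call(rbind, well_rows)
    write.csv(well_metrics, file.path(out_dir, "mea_well_metrics.csv"),
              row.names = FALSE)
    report$mea <- c(list(n_wells = nrow(well_metrics)),
                    as.list(colMeans(well_metrics[, -1])))
  }

  if ("stats" %in% cfg$stages) {
    if (is.null(sim)) stop("missing upstream product: simulate")
    st <- list()
    if (!is.null(hgp_table)) {
      lme <- fit_lme_tissue(data.frame(hgp = hgp_table$hgp,
                                       tissue_label = hgp_table$tissue_label,
                                       participant = hgp_table$participant))
      st$lme <- list(tissue_effect = lme$fixed_effect_estimate,
                     F_stat = lme$F_stat, p_value = lme$p_value)
    }
    write.csv(sim$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    km <- km_logrank(sim$cohort, reverse_km = TRUE)
    st$survival <- list(median_weeks = as.list(km$median),
                        logrank_chisq = km$logrank_chisq,
                        p_value = km$p_value,
                        median_followup_weeks = km$median_followup)
    report$stats <- st
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
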
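# Seeded synthetic-data generators. Each generator is a pure function of its
# spec (which carries the seed) and records the ground truth needed to score
# every downstream stage.

validate_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stop("invalid '", name, "': must be an integer >= ", min)
  }
  as.integer(x)
}

validate_num <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop("invalid '", name, "': must be in ", if (lo_open) "(" else "[",
                lo, ", ", hi, if (hi_open) ")" else "]")
  as.numeric(x)
}

#' Simulation specification for a speech-locked ECoG experiment
#'
#' Describes a multi-participant electrocorticography experiment in which
#' each speech onset elicits a high-gamma burst (amplitude-modulated
#' narrowband 70-110 Hz noise under a raised-cosine envelope). Tumour-labelled
#' channels scale the burst by `tumour_amplitude_ratio`; the word-frequency
#' condition shifts the burst amplitude by `condition_effect_size` noise-SD
#' units, the separation the decoding stage has to recover.
#'
#' @param n_participants,n_channels,n_trials_per_condition counts.
#' @param fraction_tumour_channels fraction of channels labelled tumour, in (0,1).
#' @param fs sampling rate in Hz; must exceed twice the upper burst band edge.
#' @param burst_band Hz pair for the burst carrier.
#' @param burst_window ms pair relative to speech onset.
#' @param tumour_amplitude_ratio burst amplitude multiplier on tumour channels
#'   (1 = no injected tissue effect).
#' @param condition_effect_size low/high-frequency word amplitude separation
#'   in noise-SD units.
#' @param noise_sd background noise SD in signal units.
#' @param seed integer seed.
#' @return an object of class `ecog_sim_spec`.
#' @export
ecog_sim_spec <- function(n_participants = 8, n_channels = 16,
                          fraction_tumour_channels = 0.5, fs = 1200,
                          n_trials_per_condition = 20,
                          burst_band = c(70, 110), burst_window = c(0, 400),
                          tumour_amplitude_ratio = 2,
                          condition_effect_size = 1, noise_sd = 1, seed = 1) {
  spec <- list(
    n_participants = validate_count(n_participants, "n_participants"),
    n_channels = validate_count(n_channels, "n_channels", min = 2),
    fraction_tumour_channels = validate_num(fraction_tumour_channels,
      "fraction_tumour_channels", 0, 1, lo_open = TRUE, hi_open = TRUE),
    fs = validate_num(fs, "fs", 0, lo_open = TRUE),
    n_trials_per_condition = validate_count(n_trials_per_condition,
      "n_trials_per_condition"),
    burst_band = sort(as.numeric(burst_band)),
    burst_window = as.numeric(burst_window) / 1000,
    tumour_amplitude_ratio = validate_num(tumour_amplitude_ratio,
      "tumour_amplitude_ratio", 0),
    condition_effect_size = validate_num(condition_effect_size,
      "condition_effect_size", -Inf, Inf),
    noise_sd = validate_num(noise_sd, "noise_sd", 0, lo_open = TRUE),
    seed = validate_count(seed, "seed", min = 0)
  )
  if (spec$fs <= 2 * spec$burst_band[2]) {
    stop("invalid 'fs': must exceed twice the upper burst band edge")
  }
  structure(spec, class = "ecog_sim_spec")
}

#' Generate a multi-participant speech-locked ECoG dataset
#'
#' @param spec an [ecog_sim_spec()].
#' @return a list with `participants` (each holding a `recording` and a
#'   `trials` table), and `truth` recording tissue labels, per-trial burst
#'   amplitudes and onsets.
#' @export
generate_ecog_dataset <- function(spec) {
  stopifnot(inherits(spec, "ecog_sim_spec"))
  seeds <- split_seeds(spec$seed, spec$n_participants)
  participants <- vector("list", spec$n_participants)
  truth <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    participants[[p]] <- with_seed(seeds[p], simulate_one_ecog(spec, p))
    truth[[p]] <- participants[[p]]$truth
    participants[[p]]$truth <- NULL
  }
  list(participants = participants, truth = truth, spec = spec)
}

simulate_one_ecog <- function(spec, p) {
  fs <- spec$fs
  n_trials <- 2L * spec$n_trials_per_condition
  iti <- 5  # s between speech onsets
  duration <- 3 + n_trials * iti + 3
  n_samp <- round(duration * fs)
  n_ch <- spec$n_channels

  n_tum <- max(1L, round(spec$fraction_tumour_channels * n_ch))
  tissue <- c(rep("tumour", n_tum), rep("non_tumour", n_ch - n_tum))
  # electrode grid on a 10-mm pitch; tumour block sits at negative y
  coords <- cbind(x = rep(seq_len(ceiling(n_ch / 4)), each = 4)[seq_len(n_ch)] * 10,
                  y = rep(1:4, length.out = n_ch) * 10 -
                    ifelse(tissue == "tumour", 60, 0),
                  z = 0)

  condition <- sample(rep(c("low_freq_word", "high_freq_word"),
                          spec$n_trials_per_condition))
  onset_s <- 3 + (seq_len(n_trials) - 1) * iti
  latency_s <- runif(n_trials, 0.5, 1.8)
  slow <- runif(n_trials) < 0.10
  latency_s[slow] <- runif(sum(slow), 2.05, 3.0)
  correct <- runif(n_trials) < 0.92

  # broadband noise plus a shared low-frequency (alpha) background: the
  # background carries most of the raw variance, as in real cortical
  # recordings, so task-responsive channels keep near-Gaussian kurtosis and
  # survive artifact screening; it is removed by the common-average
  # reference and lies far below the high-gamma analysis band
  background <- 3 * spec$noise_sd *
    butter_bandpass(rnorm(n_samp), fs, c(8, 12), order = 4)
  background <- background / sd(background) * 3 * spec$noise_sd
  signal_mat <- matrix(rnorm(n_ch * n_samp, sd = spec$noise_sd), n_ch, n_samp)
  signal_mat <- sweep(signal_mat, 2, background, "+")
  t_win <- seq(round(spec$burst_window[1] * fs),
               round(spec$burst_window[2] * fs) - 1)
  env <- 0.5 * (1 - cos(2 * pi * seq_along(t_win) / length(t_win)))  # raised cosine
  cond_shift <- ifelse(condition == "high_freq_word", 0.5, -0.5) *
    spec$condition_effect_size * spec$noise_sd
  # burst peak amplitude ~ noise SD: in-band the burst still dominates the
  # (broadband) noise, while the raw channel keeps kurtosis near Gaussian so
  # task-responsive channels survive the artifact screen
  base_amp <- spec$noise_sd
  amp_mat <- matrix(0, n_trials, n_ch)
  for (ch in seq_len(n_ch)) {
    carrier <- fir_bandpass(rnorm(n_samp), fs, spec$burst_band, order = 300)
    carrier <- carrier / sd(carrier)
    ratio <- if (tissue[ch] == "tumour") spec$tumour_amplitude_ratio else 1
    for (tr in seq_len(n_trials)) {
      amp <- max(0, (base_amp + cond_shift[tr])) * ratio
      amp_mat[tr, ch] <- amp
      idx <- round(onset_s[tr] * fs) + t_win
      signal_mat[ch, idx] <- signal_mat[ch, idx] + amp * env * carrier[idx]
    }
  }

  recording <- new_recording(
    samples = signal_mat, fs = fs,
    channel_ids = sprintf("P%02d_ch%02d", p, seq_len(n_ch)),
    channel_coords = coords, tissue_label = tissue
  )
  trials <- data.frame(onset_s = onset_s, condition = condition,
                       correct = correct, latency_s = latency_s)
  list(recording = recording, trials = trials,
       truth = list(tissue = tissue, amplitude = amp_mat,
                    condition = condition, onset_s = onset_s,
                    base_amp = base_amp))
}

#' Simulation specification for an alpha-band coupled voxel grid
#'
#' Two mirror-symmetric hemispheres of voxels on an 8-mm grid share a common
#' narrowband alpha oscillator received with per-voxel phase lags on the
#' circular lattice `{0, phase_lag, 2*phase_lag, ...}`; independent broadband
#' noise is added per voxel. Voxels in `lesion_voxel_ids` receive the
#' oscillator with amplitude multiplied by `lesion_coupling_boost`, giving
#' them the strongest band-limited coupling to the rest of the grid.
#'
#' @param n_voxels_per_hemisphere voxel count per hemisphere.
#' @param grid_spacing mm between voxel centres.
#' @param fs sampling rate, Hz.
#' @param duration recording length, s (>= 20 analysis segments required).
#' @param alpha_freq centre of the alpha band, Hz in `[8, 12]`.
#' @param base_coupling oscillator amplitude in signal units for normal voxels.
#' @param lesion_voxel_ids integer voxel ids (all in the left hemisphere,
#'   i.e. ids `1..n_voxels_per_hemisphere`).
#' @param lesion_coupling_boost amplitude multiplier `>= 1` on lesion voxels.
#' @param phase_lag lattice step of the per-voxel phase lags, radians.
#' @param noise_sd per-voxel noise SD.
#' @param seed integer seed.
#' @return an object of class `voxel_sim_spec`.
#' @export
voxel_sim_spec <- function(n_voxels_per_hemisphere = 250, grid_spacing = 8,
                           fs = 200, duration = 60, alpha_freq = 10,
                           base_coupling = 0.25,
                           lesion_voxel_ids = integer(0),
                           lesion_coupling_boost = 1, phase_lag = pi / 4,
                           noise_sd = 1, seed = 1) {
  spec <- list(
    n_voxels_per_hemisphere = validate_count(n_voxels_per_hemisphere,
      "n_voxels_per_hemisphere", min = 4),
    grid_spacing = validate_num(grid_spacing, "grid_spacing", 0, lo_open = TRUE),
    fs = validate_num(fs, "fs", 0, lo_open = TRUE),
    duration = validate_num(duration, "duration", 0, lo_open = TRUE),
    alpha_freq = validate_num(alpha_freq, "alpha_freq", 8, 12),
    base_coupling = validate_num(base_coupling, "base_coupling", 0, lo_open = TRUE),
    lesion_voxel_ids = as.integer(lesion_voxel_ids),
    lesion_coupling_boost = validate_num(lesion_coupling_boost,
      "lesion_coupling_boost", 1),
    phase_lag = validate_num(phase_lag, "phase_lag", 0, 2 * pi, lo_open = TRUE),
    noise_sd = validate_num(noise_sd, "noise_sd", 0, lo_open = TRUE),
    seed = validate_count(seed, "seed", min = 0)
  )
  if (length(spec$lesion_voxel_ids) &&
      (any(spec$lesion_voxel_ids < 1) ||
       any(spec$lesion_voxel_ids > spec$n_voxels_per_hemisphere))) {
    stop("lesion voxel ids outside the left-hemisphere grid")
  }
  if (spec$duration * spec$fs < 20 * spec$fs) {
    stop("duration must allow at least 20 one-second analysis segments")
  }
  structure(spec, class = "voxel_sim_spec")
}

#' Generate a mirror-symmetric coupled voxel-grid time series
#'
#' @param spec a [voxel_sim_spec()].
#' @return a `voxel_series` object: `series` (voxels x time), `fs`,
#'   `grid_index`, `spacing`, `hemisphere`, `mirror_pair`, `tumour_mask`,
#'   `duration`, plus a `truth` record (per-voxel coupling amplitude, phase).
#' @export
generate_voxel_dataset <- function(spec) {
  stopifnot(inherits(spec, "voxel_sim_spec"))
  n_h <- spec$n_voxels_per_hemisphere
  n_vox <- 2L * n_h
  n_samp <- round(spec$duration * spec$fs)

  # cubic-ish grid per hemisphere; right hemisphere mirrors x
  nx <- ceiling(n_h^(1 / 3)); ny <- ceiling(sqrt(n_h / nx)); nz <- ceiling(n_h / (nx * ny))
  idx <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))[seq_len(n_h), ]
  grid_index <- rbind(cbind(-idx$ix, idx$iy, idx$iz),
                      cbind(idx$ix, idx$iy, idx$iz))
  hemisphere <- rep(c("left", "right"), each = n_h)
  mirror_pair <- c(seq_len(n_h) + n_h, seq_len(n_h))
  tumour_mask <- rep(FALSE, n_vox)
  tumour_mask[spec$lesion_voxel_ids] <- TRUE

  seeds <- split_seeds(spec$seed, n_vox + 1L)
  band <- c(spec$alpha_freq - 2, spec$alpha_freq + 2)
  s <- with_seed(seeds[n_vox + 1L], {
    z <- butter_bandpass(rnorm(n_samp), spec$fs, band, order = 4)
    z / sd(z)
  })
  a <- analytic_signal(s)

  m <- max(1L, round(2 * pi / spec$phase_lag))
  phases <- ((seq_len(n_vox) - 1L) %% m) * spec$phase_lag
  coupling <- rep(spec$base_coupling, n_vox)
  coupling[tumour_mask] <- coupling[tumour_mask] * spec$lesion_coupling_boost

  series <- matrix(0, n_vox, n_samp)
  for (v in seq_len(n_vox)) {
    series[v, ] <- coupling[v] * Re(a * exp(-1i * phases[v])) +
      with_seed(seeds[v], rnorm(n_samp, sd = spec$noise_sd))
  }

  structure(list(
    series = series, fs = spec$fs, grid_index = grid_index,
    spacing = spec$grid_spacing, hemisphere = hemisphere,
    mirror_pair = mirror_pair, tumour_mask = tumour_mask,
    duration = spec$duration,
    truth = list(coupling = coupling, phase = phases, spec = spec)
  ), class = "voxel_series")
}

#' Simulation specification for MEA spike rasters
#'
#' Background activity is homogeneous Poisson per electrode; network bursts
#' are scheduled explicitly as `(time_s, electrode_fraction, n_spikes)` rows,
#' each burst distributing its spikes over the participating electrodes at a
#' regular 20 ms within-burst spacing jittered by `within_burst_jitter_sd`.
#'
#' @param n_wells,n_electrodes_per_well counts.
#' @param duration recording length, s.
#' @param background_rate Hz per electrode.
#' @param network_burst_schedule data.frame with columns `time_s`,
#'   `electrode_fraction`, `n_spikes` (may have zero rows).
#' @param within_burst_jitter_sd ms.
#' @param emit_voltage also synthesise raw voltage traces with embedded
#'   biphasic spikes.
#' @param spike_snr spike amplitude as a multiple of the voltage noise SD.
#' @param voltage_fs voltage sampling rate, Hz.
#' @param seed integer seed.
#' @return an object of class `raster_sim_spec`.
#' @export
raster_sim_spec <- function(n_wells = 1, n_electrodes_per_well = 16,
                            duration = 1800, background_rate = 0.1,
                            network_burst_schedule = NULL,
                            within_burst_jitter_sd = 2, emit_voltage = FALSE,
                            spike_snr = 10, voltage_fs = 12500, seed = 1) {
  if (is.null(network_burst_schedule)) {
    network_burst_schedule <- data.frame(time_s = numeric(0),
                                         electrode_fraction = numeric(0),
                                         n_spikes = numeric(0))
  }
  spec <- list(
    n_wells = validate_count(n_wells, "n_wells"),
    n_electrodes_per_well = validate_count(n_electrodes_per_well,
      "n_electrodes_per_well", min = 2),
    duration = validate_num(duration, "duration", 0, lo_open = TRUE),
    background_rate = validate_num(background_rate, "background_rate", 0),
    network_burst_schedule = network_burst_schedule,
    within_burst_jitter_sd = validate_num(within_burst_jitter_sd,
      "within_burst_jitter_sd", 0) / 1000,
    emit_voltage = isTRUE(emit_voltage),
    spike_snr = validate_num(spike_snr, "spike_snr", 0, lo_open = TRUE),
    voltage_fs = validate_num(voltage_fs, "voltage_fs", 0, lo_open = TRUE),
    seed = validate_count(seed, "seed", min = 0)
  )
  sched <- spec$network_burst_schedule
  assert_fields(sched, c("time_s", "electrode_fraction", "n_spikes"),
                "network_burst_schedule")
  if (nrow(sched) && (any(sched$time_s < 0) || any(sched$time_s >= spec$duration))) {
    stop("scheduled burst times must lie within [0, duration)")
  }
  structure(spec, class = "raster_sim_spec")
}

#' Generate MEA spike rasters (and optionally raw voltage traces)
#'
#' @param spec a [raster_sim_spec()].
#' @return a list with `spikes` (a `spike_train_set`), `voltage` (list of
#'   electrodes x samples matrices per well, or NULL) and `truth` (the burst
#'   schedule with participating electrodes and true spike times).
#' @export
generate_spike_data <- function(spec) {
  stopifnot(inherits(spec, "raster_sim_spec"))
  seeds <- split_seeds(spec$seed, spec$n_wells)
  wells <- vector("list", spec$n_wells)
  voltage <- if (spec$emit_voltage) vector("list", spec$n_wells) else NULL
  truth <- vector("list", spec$n_wells)
  for (w in seq_len(spec$n_wells)) {
    out <- with_seed(seeds[w], simulate_one_well(spec))
    wells[[w]] <- out$trains
    truth[[w]] <- out$truth
    if (spec$emit_voltage) voltage[[w]] <- out$voltage
  }
  names(wells) <- sprintf("well%02d", seq_len(spec$n_wells))
  spikes <- structure(list(spikes = wells, duration = spec$duration,
                           n_electrodes_per_well = spec$n_electrodes_per_well),
                      class = "spike_train_set")
  list(spikes = spikes, voltage = voltage, truth = truth, spec = spec)
}

simulate_one_well <- function(spec) {
  n_e <- spec$n_electrodes_per_well
  trains <- vector("list", n_e)
  for (e in seq_len(n_e)) {
    n_bg <- rbinom(1, round(spec$duration * 1000),
                   min(1, spec$background_rate / 1000))
    trains[[e]] <- sort(runif(n_bg, 0, spec$duration))
  }
  sched <- spec$network_burst_schedule
  sched_truth <- NULL
  if (nrow(sched)) {
    parts <- vector("list", nrow(sched))
    for (b in seq_len(nrow(sched))) {
      n_part <- max(1L, round(sched$electrode_fraction[b] * n_e))
      elec <- sort(sample.int(n_e, n_part))
      per_e <- round(sched$n_spikes[b] / n_part)
      for (e in elec) {
        tt <- sched$time_s[b] + (seq_len(per_e) - 1) * 0.020 +
          rnorm(per_e, sd = spec$within_burst_jitter_sd)
        trains[[e]] <- c(trains[[e]], tt)
      }
      parts[[b]] <- elec
    }
    sched_truth <- cbind(sched, n_participating = lengths(parts))
    attr(sched_truth, "electrodes") <- parts
  }
  trains <- lapply(trains, function(tt) {
    tt <- sort(tt[tt >= 0 & tt < spec$duration])
    tt[!duplicated(tt)]
  })
  names(trains) <- sprintf("e%02d", seq_len(n_e))

  voltage <- NULL
  if (spec$emit_voltage) {
    fs <- spec$voltage_fs
    n_samp <- round(spec$duration * fs)
    tmpl_t <- seq(0, 0.001 - 1 / fs, by = 1 / fs)
    template <- sin(2 * pi * tmpl_t / 0.001)  # 1 ms biphasic pulse
    voltage <- matrix(rnorm(n_e * n_samp), n_e, n_samp)
    for (e in seq_len(n_e)) {
      for (tt in trains[[e]]) {
        i0 <- round(tt * fs) + 1L
        idx <- i0:(i0 + length(template) - 1L)
        keep <- idx <= n_samp
        voltage[e, idx[keep]] <- voltage[e, idx[keep]] +
          spec$spike_snr * template[keep]
      }
    }
  }
  list(trains = trains, voltage = voltage,
       truth = list(schedule = sched_truth, spike_times = trains))
}

#' Simulation specification for an aperiodic + peaks power spectrum
#'
#' Tabulates `log10 P(f) = offset_b - log10(knee_k + f^exponent_chi)` plus
#' Gaussian oscillatory peaks and optional log-space noise on a fixed grid.
#'
#' @param offset_b aperiodic offset, log10-power units.
#' @param knee_k knee parameter, `Hz^exponent` units, `>= 0`.
#' @param exponent_chi aperiodic exponent, `>= 0`.
#' @param peaks data.frame with columns `centre_hz`, `height_log10`,
#'   `width_hz` (may have zero rows).
#' @param freq_range Hz pair.
#' @param freq_step grid step, Hz.
#' @param noise_sd_log SD of additive log10-space noise.
#' @param seed integer seed.
#' @return an object of class `spectrum_sim_spec`.
#' @export
spectrum_sim_spec <- function(offset_b = 1, knee_k = 0, exponent_chi = 2,
                              peaks = NULL, freq_range = c(1, 50),
                              freq_step = 0.5, noise_sd_log = 0, seed = 1) {
  if (is.null(peaks)) {
    peaks <- data.frame(centre_hz = numeric(0), height_log10 = numeric(0),
                        width_hz = numeric(0))
  }
  assert_fields(peaks, c("centre_hz", "height_log10", "width_hz"), "peaks")
  spec <- list(
    offset_b = validate_num(offset_b, "offset_b"),
    knee_k = validate_num(knee_k, "knee_k", 0),
    exponent_chi = validate_num(exponent_chi, "exponent_chi", 0),
    peaks = peaks,
    freq_range = sort(as.numeric(freq_range)),
    freq_step = validate_num(freq_step, "freq_step", 0, lo_open = TRUE),
    noise_sd_log = validate_num(noise_sd_log, "noise_sd_log", 0),
    seed = validate_count(seed, "seed", min = 0)
  )
  if (nrow(peaks) && (any(peaks$centre_hz < spec$freq_range[1]) ||
                      any(peaks$centre_hz > spec$freq_range[2]))) {
    stop("peak centres must lie inside freq_range")
  }
  structure(spec, class = "spectrum_sim_spec")
}

#' Generate a synthetic power spectrum with known aperiodic parameters
#'
#' @param spec a [spectrum_sim_spec()].
#' @return a `spectrum_estimate` (freqs, psd) with the generating parameters
#'   attached as `truth`.
#' @export
generate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_sim_spec"))
  f <- seq(spec$freq_range[1], spec$freq_range[2], by = spec$freq_step)
  logp <- spec$offset_b - log10(spec$knee_k + f^spec$exponent_chi)
  if (nrow(spec$peaks)) {
    for (i in seq_len(nrow(spec$peaks))) {
      pk <- spec$peaks[i, ]
      logp <- logp + pk$height_log10 *
        exp(-(f - pk$centre_hz)^2 / (2 * pk$width_hz^2))
    }
  }
  if (spec$noise_sd_log > 0) {
    logp <- logp + with_seed(spec$seed, rnorm(length(f), sd = spec$noise_sd_log))
  }
  structure(list(freqs = f, psd = 10^logp, n_tapers = NA_integer_, fs = NA_real_,
                 truth = spec),
            class = "spectrum_estimate")
}

#' Simulation specification for a two-group right-censored survival cohort
#'
#' Event times are exponential with the stated per-group medians; censoring
#' is independent exponential with its rate set so that the expected
#' censored fraction equals `censoring_fraction`.
#'
#' @param n_per_group subjects per group.
#' @param median_survival_per_group numeric vector of per-group median
#'   survival times, weeks.
#' @param censoring_fraction fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_per_group = 100,
                            median_survival_per_group = c(71, 123),
                            censoring_fraction = 0.2, seed = 1) {
  if (any(median_survival_per_group <= 0)) stop("medians must be > 0")
  structure(list(
    n_per_group = validate_count(n_per_group, "n_per_group"),
    median_survival_per_group = as.numeric(median_survival_per_group),
    censoring_fraction = validate_num(censoring_fraction,
      "censoring_fraction", 0, 1, hi_open = TRUE),
    seed = validate_count(seed, "seed", min = 0)
  ), class = "cohort_sim_spec")
}

#' Generate a right-censored survival cohort
#'
#' @param spec a [cohort_sim_spec()].
#' @return data.frame with `id`, `group`, `time_weeks`, `event` plus a
#'   `truth` attribute holding the generating medians.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    groups <- paste0("g", seq_along(spec$median_survival_per_group))
    out <- do.call(rbind, lapply(seq_along(groups), function(g) {
      rate <- log(2) / spec$median_survival_per_group[g]
      t_ev <- rexp(spec$n_per_group, rate)
      q <- spec$censoring_fraction
      if (q > 0) {
        # exponential censoring with P(C < T) = q, independent of T
        t_cens <- rexp(spec$n_per_group, rate * q / (1 - q))
      } else {
        t_cens <- rep(Inf, spec$n_per_group)
      }
      data.frame(group = groups[g],
                 time_weeks = pmax(pmin(t_ev, t_cens), 1e-9),
                 event = as.integer(t_ev <= t_cens))
    }))
    out <- cbind(id = seq_len(nrow(out)), out)
    attr(out, "truth") <- list(median = spec$median_survival_per_group)
    out
  })
}

#' Build a regular network-burst schedule
#'
#' Convenience helper for [raster_sim_spec()]: `n` bursts evenly spaced over
#' the recording.
#'
#' @param n number of bursts.
#' @param duration recording length, s.
#' @param electrode_fraction participating electrode fraction per burst.
#' @param n_spikes spikes per burst.
#' @return a schedule data.frame.
#' @export
regular_burst_schedule <- function(n, duration, electrode_fraction = 0.5,
                                   n_spikes = 80) {
  data.frame(time_s = (seq_len(n) - 0.5) * duration / n,
             electrode_fraction = electrode_fraction, n_spikes = n_spikes)
}
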
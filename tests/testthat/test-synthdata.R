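# Seeded generators: determinism, ground-truth bookkeeping, closed forms.

test_that("every generator is a pure function of its spec and seed", {
  sp <- ecog_sim_spec(n_participants = 2, n_channels = 4,
                      n_trials_per_condition = 3, seed = 5)
  a <- generate_ecog_dataset(sp)
  b <- generate_ecog_dataset(sp)
  expect_identical(a$participants[[1]]$recording$samples,
                   b$participants[[1]]$recording$samples)
  expect_identical(a$participants[[2]]$trials, b$participants[[2]]$trials)

  vs <- voxel_sim_spec(n_voxels_per_hemisphere = 10, duration = 20, seed = 3)
  expect_identical(generate_voxel_dataset(vs)$series,
                   generate_voxel_dataset(vs)$series)

  rs <- raster_sim_spec(duration = 60, background_rate = 1,
                        network_burst_schedule =
                          regular_burst_schedule(2, 60), seed = 8)
  expect_identical(generate_spike_data(rs)$spikes$spikes,
                   generate_spike_data(rs)$spikes$spikes)

  ss <- spectrum_sim_spec(noise_sd_log = 0.05, seed = 2)
  expect_identical(generate_spectrum(ss)$psd, generate_spectrum(ss)$psd)

  cs <- cohort_sim_spec(n_per_group = 20, seed = 9)
  expect_identical(generate_cohort(cs), generate_cohort(cs))
})

test_that("per-participant streams are stable under count changes", {
  a <- generate_ecog_dataset(ecog_sim_spec(n_participants = 2, n_channels = 4,
                                           n_trials_per_condition = 3,
                                           seed = 5))
  b <- generate_ecog_dataset(ecog_sim_spec(n_participants = 3, n_channels = 4,
                                           n_trials_per_condition = 3,
                                           seed = 5))
  expect_identical(a$participants[[1]]$recording$samples,
                   b$participants[[1]]$recording$samples)
  expect_identical(a$participants[[2]]$recording$samples,
                   b$participants[[2]]$recording$samples)
})

test_that("ecog generator validates fields by name and records ground truth", {
  expect_error(ecog_sim_spec(fs = 180), "fs")
  expect_error(ecog_sim_spec(fraction_tumour_channels = 0),
               "fraction_tumour_channels")
  expect_error(ecog_sim_spec(n_trials_per_condition = 0),
               "n_trials_per_condition")
  ds <- generate_ecog_dataset(ecog_sim_spec(n_participants = 1,
                                            n_channels = 6,
                                            n_trials_per_condition = 4,
                                            seed = 1))
  rec <- ds$participants[[1]]$recording
  expect_setequal(unique(rec$tissue_label), c("tumour", "non_tumour"))
  expect_equal(dim(rec$channel_coords), c(6, 3))
  tr <- ds$participants[[1]]$trials
  expect_true(all(diff(tr$onset_s) > 0))
  expect_true(all(tr$latency_s >= 0))
  expect_setequal(names(ds$truth[[1]])[1:4],
                  c("tissue", "amplitude", "condition", "onset_s"))
})

test_that("voxel generator builds a mirror-symmetric grid with lesion mask", {
  vs <- voxel_sim_spec(n_voxels_per_hemisphere = 12, duration = 20,
                       lesion_voxel_ids = 1:3, lesion_coupling_boost = 2,
                       seed = 1)
  vx <- generate_voxel_dataset(vs)
  n <- nrow(vx$series)
  expect_equal(n, 24)
  # mirror pairing is an involution across hemispheres
  expect_equal(vx$mirror_pair[vx$mirror_pair], seq_len(n))
  expect_true(all(vx$hemisphere[vx$mirror_pair] != vx$hemisphere))
  expect_equal(which(vx$tumour_mask), 1:3)
  expect_equal(vx$truth$coupling[1:3], rep(0.25 * 2, 3))
  expect_error(voxel_sim_spec(n_voxels_per_hemisphere = 10, duration = 20,
                              lesion_voxel_ids = 11),
               "lesion")
  expect_error(voxel_sim_spec(n_voxels_per_hemisphere = 10, duration = 10),
               "segments")
})

test_that("boosted lesion voxels carry the strongest band-limited coupling", {
  vs <- voxel_sim_spec(n_voxels_per_hemisphere = 20, duration = 30,
                       lesion_voxel_ids = 1:4, lesion_coupling_boost = 3,
                       seed = 6)
  vx <- generate_voxel_dataset(vs)
  ic <- pairwise_imaginary_coherence(vx)
  mean_ic <- rowSums(ic) / (nrow(ic) - 1)
  expect_true(min(mean_ic[1:4]) > max(mean_ic[-(1:4)]))
})

test_that("spike generator honours schedule, sorting and silence", {
  none <- generate_spike_data(raster_sim_spec(duration = 30,
                                              background_rate = 0, seed = 1))
  expect_true(all(lengths(none$spikes$spikes[[1]]) == 0))

  sched <- regular_burst_schedule(3, 120, electrode_fraction = 0.5,
                                  n_spikes = 40)
  sd_ <- generate_spike_data(raster_sim_spec(duration = 120,
                                             background_rate = 0.5,
                                             network_burst_schedule = sched,
                                             seed = 4))
  trains <- sd_$spikes$spikes[[1]]
  expect_true(all(vapply(trains, function(tt) !is.unsorted(tt, strictly = TRUE),
                         logical(1))))
  expect_true(all(unlist(trains) >= 0 & unlist(trains) < 120))
  expect_equal(nrow(sd_$truth[[1]]$schedule), 3)
  expect_error(raster_sim_spec(duration = 60,
                               network_burst_schedule =
                                 data.frame(time_s = 70,
                                            electrode_fraction = 0.5,
                                            n_spikes = 50)),
               "within")
})

test_that("spike generator embeds detectable biphasic waveforms on request", {
  sd_ <- generate_spike_data(raster_sim_spec(n_electrodes_per_well = 2,
                                             duration = 10,
                                             background_rate = 2,
                                             emit_voltage = TRUE,
                                             spike_snr = 10, seed = 2))
  v <- sd_$voltage[[1]]
  expect_equal(dim(v), c(2, 10 * 12500))
  tt <- sd_$truth[[1]]$spike_times[[1]]
  peak_idx <- round(tt[1] * 12500) + 4  # template peak ~0.25 ms after onset
  expect_gt(abs(v[1, peak_idx]), 5)
})

test_that("spectrum generator matches its closed form", {
  ss <- spectrum_sim_spec(offset_b = 1.2, knee_k = 5, exponent_chi = 1.5)
  sp <- generate_spectrum(ss)
  expect_equal(log10(sp$psd), 1.2 - log10(5 + sp$freqs^1.5), tolerance = 1e-12)
  pk <- data.frame(centre_hz = 40, height_log10 = 0.5, width_hz = 4)
  sp2 <- generate_spectrum(spectrum_sim_spec(offset_b = 1.2, knee_k = 5,
                                             exponent_chi = 1.5, peaks = pk))
  gauss <- 0.5 * exp(-(sp2$freqs - 40)^2 / (2 * 16))
  expect_equal(log10(sp2$psd) - log10(sp$psd), gauss, tolerance = 1e-12)
  expect_error(spectrum_sim_spec(peaks = data.frame(centre_hz = 80,
                                                    height_log10 = 1,
                                                    width_hz = 2)),
               "inside freq_range")
})

test_that("cohort generator delivers stated medians under censoring", {
  co <- generate_cohort(cohort_sim_spec(n_per_group = 50, seed = 3))
  expect_equal(nrow(co), 100)
  expect_true(all(co$time_weeks > 0))
  expect_setequal(unique(co$group), c("g1", "g2"))
  # consistency of the KM median under independent censoring
  hits <- unlist(lapply(1:25, function(s) {
    km <- km_logrank(generate_cohort(cohort_sim_spec(n_per_group = 400,
                                                     seed = s)))
    abs(km$median - c(71, 123)) / c(71, 123) <= 0.15
  }))
  expect_gte(mean(hits), 0.9)
})
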
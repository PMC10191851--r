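# ECoG stage: tumour-contact labelling, channel/trial screening, epoching,
# high-gamma power and ERSP.

test_that("electrodes are labelled by inclusive 10 mm distance to the core", {
  core <- rbind(c(0, 0, 0), c(20, 0, 0))
  coords <- rbind(c(8, 0, 0), c(0, 12, 0), c(10, 0, 0), c(35, 0, 0))
  lab <- label_electrodes(coords, core)
  expect_equal(lab$tissue_label,
               c("tumour", "non_tumour", "tumour", "non_tumour"))
  expect_equal(lab$distance_mm, c(8, 12, 10, 15), tolerance = 1e-12)
  expect_error(label_electrodes(coords, core[0, ]), "empty")
})

test_that("kurtosis screen keeps Gaussian channels, drops heavy tails", {
  set.seed(4)
  n <- 1e5
  gauss <- rnorm(n)
  laplace <- rexp(n) * sample(c(-1, 1), n, replace = TRUE)  # kurtosis 6
  const <- rep(1, n)
  rec <- new_recording(rbind(gauss, laplace, const), fs = 1000)
  out <- reject_noisy_channels(rec)
  # oracle: direct moment computation
  k_direct <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  expect_equal(unname(out$kurtosis[1]), k_direct(gauss))
  expect_equal(unname(out$kurtosis[2]), k_direct(laplace))
  expect_equal(out$recording$channel_ids, "ch01")
  expect_setequal(out$rejected$reason, c("kurtosis", "degenerate"))
  expect_error(reject_noisy_channels(new_recording(matrix(rnorm(10), 1),
                                                   fs = 10)),
               "2 channels")
})

test_that("trial selection applies the correctness and 2 s latency rules", {
  tr <- data.frame(onset_s = 1:5,
                   condition = "other",
                   correct = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                   latency_s = c(0.8, 2.5, 1.0, 2.0, 1.1))
  kept <- select_trials(tr)
  expect_equal(kept$onset_s, c(1, 4, 5))  # exactly-2 s trial is retained
  expect_equal(attr(kept, "rejections"), c(incorrect = 1, slow = 1))
  all_ok <- data.frame(onset_s = 1:3, condition = "other", correct = TRUE,
                       latency_s = 0.5)
  expect_equal(nrow(select_trials(all_ok)), 3)
})

test_that("speech-locked epochs are half-open [-2, 2) with onset at 2*fs", {
  fs <- 1200
  n <- 10 * fs
  x <- matrix(0, 1, n)
  onset <- 5.0
  x[1, round(onset * fs) + 1] <- 1  # impulse at the onset sample (0-based)
  rec <- new_recording(x, fs)
  tr <- data.frame(onset_s = c(onset, 1.0), condition = "other",
                   correct = TRUE, latency_s = 1)
  ep <- epoch_speech_locked(rec, tr)
  expect_equal(dim(ep$data), c(1, 1, 4 * fs))
  expect_equal(attr(ep, "dropped"), 2L)  # onset 1 s from the edge
  expect_equal(which(ep$data[1, 1, ] == 1) - 1, 2 * fs)  # 0-based index 2400
  tr_bad <- data.frame(onset_s = 0.5, condition = "other", correct = TRUE,
                       latency_s = 1)
  expect_error(epoch_speech_locked(rec, tr_bad), "no trials")
})

test_that("HGp recovers in-band power and rejects out-of-band energy", {
  fs <- 1200
  t <- seq(0, 16 - 1 / fs, by = 1 / fs)
  rec <- new_recording(rbind(sin(2 * pi * 90 * t), sin(2 * pi * 20 * t),
                             0 * t), fs)
  tr <- data.frame(onset_s = c(4, 8, 12), condition = "other", correct = TRUE,
                   latency_s = 1)
  hgp <- compute_hgp(epoch_speech_locked(rec, tr), reference = "none")
  expect_true(all(hgp$values >= 0))
  edge <- round(0.25 * fs)
  core <- (edge + 1):(dim(hgp$values)[3] - edge)
  expect_lt(max(abs(hgp$values[1, 1, core] - 1)), 0.02)
  expect_lt(mean(hgp$values[1, 2, core]), 0.01 * mean(hgp$values[1, 1, core]))
  expect_equal(max(hgp$values[, 3, ]), 0)
  expect_error(compute_hgp(epoch_speech_locked(rec, tr), band = c(500, 700)),
               "Nyquist")
})

test_that("the HGp filter chain is shift-covariant (zero phase)", {
  fs <- 1200
  n <- 12 * fs
  x <- matrix(0, 2, n)
  x[1, 6 * fs + 1] <- 1
  k <- 37
  x[2, 6 * fs + 1 + k] <- 1  # same impulse delayed k samples
  tr <- data.frame(onset_s = 6, condition = "other", correct = TRUE,
                   latency_s = 1)
  hgp <- compute_hgp(epoch_speech_locked(new_recording(x, fs), tr),
                     reference = "none")
  a <- hgp$values[1, 1, ]
  b <- hgp$values[1, 2, ]
  expect_equal(which.max(b) - which.max(a), k)
})

test_that("ERSP output is z-scored per trial at exactly 100 Hz", {
  fs <- 1200
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  set.seed(7)
  x <- matrix(rnorm(2 * length(t), sd = 0.3), 2)
  tr <- data.frame(onset_s = c(5, 10, 15), condition = "other",
                   correct = TRUE, latency_s = 1)
  for (on in tr$onset_s) {   # 120 Hz burst spanning 0-300 ms post onset
    idx <- round(on * fs):(round(on * fs) + 0.3 * fs)
    x[1, idx] <- x[1, idx] + 3 * sin(2 * pi * 120 * idx / fs)
  }
  er <- compute_ersp(new_recording(x, fs), tr)
  expect_equal(er$fs, 100)
  expect_equal(dim(er$values)[3], 400)
  for (i in 1:3) {
    expect_lt(abs(mean(er$values[i, 1, ])), 1e-9)
    expect_lt(abs(sd(er$values[i, 1, ]) - 1), 1e-9)
    peak_t <- (which.max(er$values[i, 1, ]) - 1) / 100 - 2
    expect_gte(peak_t, 0)
    expect_lte(peak_t, 0.3)
  }
  expect_false(any(er$degenerate))
})

test_that("ERSP flags zero-variance trials as degenerate", {
  fs <- 1200
  x <- matrix(0, 1, 10 * fs)
  tr <- data.frame(onset_s = 5, condition = "other", correct = TRUE,
                   latency_s = 1)
  er <- compute_ersp(new_recording(x, fs), tr)
  expect_true(er$degenerate[1, 1])
  expect_true(all(is.na(er$values[1, 1, ])))
})

test_that("tumour channels show higher task HGp when an effect is injected", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    ds <- generate_ecog_dataset(ecog_sim_spec(n_participants = 1,
                                              n_channels = 6,
                                              n_trials_per_condition = 4,
                                              tumour_amplitude_ratio = 2,
                                              seed = 100 + s))
    part <- ds$participants[[1]]
    scr <- reject_noisy_channels(part$recording)
    ep <- epoch_speech_locked(scr$recording, select_trials(part$trials))
    cm <- hgp_channel_means(compute_hgp(ep))
    tum <- cm$hgp_mean[cm$tissue_label == "tumour"]
    non <- cm$hgp_mean[cm$tissue_label == "non_tumour"]
    hits <- hits + sum(outer(tum, non, ">"))
    total <- total + length(tum) * length(non)
  }
  expect_gte(hits / total, 0.95)
})
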
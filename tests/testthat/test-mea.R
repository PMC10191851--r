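# MEA analytics: spike detection, bursts, network bursts, rates, AUNCC.

test_that("burst detection follows the 5-spike / 100 ms run rule", {
  b1 <- detect_bursts(seq(0, by = 0.05, length.out = 6))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_spikes, 6L)
  expect_equal(b1$start_s, 0)
  expect_equal(b1$end_s, 0.25)

  expect_equal(nrow(detect_bursts(seq(0, by = 0.05, length.out = 4))), 0)

  two <- c(seq(0, by = 0.05, length.out = 5),
           seq(0.5, by = 0.05, length.out = 5))  # 300 ms gap at 0.2 -> 0.5
  b2 <- detect_bursts(two)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_spikes, c(5L, 5L))
  expect_error(detect_bursts(c(2, 1)), "sorted")
})

test_that("burst detector equals the exhaustive run-scan oracle", {
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(0:40, 1)
    train <- sort(runif(n, 0, 5))
    expect_identical(detect_bursts(train), burst_oracle(train))
  }
})

test_that("network bursts need 35% of electrodes and 50 spikes", {
  mk <- function(n_elec, per_elec) {
    tr <- rep(list(numeric(0)), 16)
    for (e in seq_len(n_elec)) tr[[e]] <- 100 + (seq_len(per_elec) - 1) * 0.05
    names(tr) <- sprintf("e%02d", 1:16)
    tr
  }
  act <- rep(TRUE, 16)  # ceil(0.35 * 16) = 6 electrodes needed
  expect_equal(nrow(detect_network_bursts(mk(6, 10), act)), 1)   # 60 spikes
  expect_equal(nrow(detect_network_bursts(mk(5, 12), act)), 0)   # 5 < 6
  expect_equal(nrow(detect_network_bursts(mk(6, 7), act)), 0)    # 42 < 50
  nb <- detect_network_bursts(mk(7, 10), act)
  expect_equal(nb$n_electrodes, 7L)
  expect_equal(nb$total_spikes, 70L)
  expect_error(detect_network_bursts(mk(6, 10), rep(FALSE, 16)), "active")
})

test_that("scheduled network bursts are recovered exactly end to end", {
  spec <- raster_sim_spec(duration = 600, background_rate = 0.2,
                          network_burst_schedule =
                            regular_burst_schedule(10, 600,
                                                   electrode_fraction = 0.5,
                                                   n_spikes = 80),
                          seed = 3)
  sd_ <- generate_spike_data(spec)
  trains <- sd_$spikes$spikes[[1]]
  met <- summarize_firing(trains, duration = 600)
  nb <- detect_network_bursts(trains, met$active)
  expect_equal(nrow(nb), 10)
})

test_that("spike detection is sensitive at 10x noise with few false alarms", {
  spec <- raster_sim_spec(n_electrodes_per_well = 2, duration = 60,
                          background_rate = 100 / 60, emit_voltage = TRUE,
                          spike_snr = 10, seed = 5)
  sv <- generate_spike_data(spec)
  det <- detect_spikes(sv$voltage[[1]], fs = 12500)
  for (e in 1:2) {
    true_t <- sv$truth[[1]]$spike_times[[e]]
    det_t <- det$spikes[[1]][[e]]
    hit <- vapply(true_t, function(tt) any(abs(det_t - tt) <= 0.001),
                  logical(1))
    expect_gte(mean(hit), 0.99)
  }
  set.seed(6)
  noise <- matrix(rnorm(2 * 60 * 12500), 2)
  fp <- vapply(detect_spikes(noise, fs = 12500)$spikes[[1]], length,
               numeric(1)) / 60
  expect_true(all(fp <= 0.05))
  expect_warning(out <- detect_spikes(matrix(0, 1, 12500), fs = 12500),
                 "zero-variance")
  expect_length(out$spikes[[1]][[1]], 0)
})

test_that("firing summaries implement the stated rates and activity rule", {
  dur <- 1800
  trains <- list(e01 = seq(0, dur - 0.5, by = 0.5),     # 3600 spikes -> 2 Hz
                 e02 = seq(0, dur - 1, length.out = 100),  # 3.33/min
                 e03 = seq(0, dur - 1, length.out = 200),  # 6.67/min
                 e04 = numeric(0))
  met <- summarize_firing(trains, duration = dur)
  expect_equal(unname(met$mfr["e01"]), 2)
  expect_equal(unname(met$active), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(summarize_firing(trains, duration = 0), "positive")

  # two active electrodes at 2 and 4 Hz -> wMFR 3 Hz (mean over active)
  tr2 <- list(e01 = seq(0, 99.9, by = 0.5), e02 = seq(0, 99.95, by = 0.25),
              e03 = numeric(0))
  met2 <- summarize_firing(tr2, duration = 100)
  expect_equal(met2$wmfr, 3)
  met2l <- summarize_firing(tr2, duration = 100, wmfr_literal = TRUE)
  expect_equal(met2l$wmfr, 4)  # well rate 2 Hz x 2 active electrodes
})

test_that("identical trains give unit normalized cross-correlograms", {
  tt <- sort(runif(200, 0, 100))
  trains <- list(e01 = tt, e02 = tt, e03 = tt)
  au <- compute_auncc(trains, duration = 100)
  zero_lag <- which(au$lags_s == 0)
  expect_true(all(abs(au$rho[, zero_lag] - 1) < 1e-12))
  # pairwise correlogram equals the autocorrelogram at every lag
  auto <- au$rho[1, ]
  for (p in seq_len(nrow(au$rho))) expect_equal(au$rho[p, ], auto)
  expect_error(compute_auncc(trains[1], duration = 100), "2 active")
})

test_that("normalized correlograms live in [0, 1] and track synchrony", {
  set.seed(9)
  base <- sort(runif(600, 0, 300))
  a_ident <- compute_auncc(jittered_trains(base, 0), 300)
  a_j5 <- compute_auncc(jittered_trains(base, 0.005), 300)
  a_j20 <- compute_auncc(jittered_trains(base, 0.020), 300)
  pois <- lapply(1:8, function(i) sort(runif(600, 0, 300)))
  names(pois) <- sprintf("e%02d", 1:8)
  a_pois <- compute_auncc(pois, 300)
  for (a in list(a_ident, a_j5, a_j20, a_pois)) {
    expect_true(all(a$rho >= 0 & a$rho <= 1 + 1e-12))
  }
  expect_gt(a_ident$auncc, a_j5$auncc)
  expect_gt(a_j5$auncc, a_j20$auncc)
  expect_gt(a_j20$auncc, a_pois$auncc)
  expect_lte(a_pois$auncc, 0.1 * a_ident$auncc)
})
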
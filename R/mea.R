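# Multi-electrode-array analytics: spike detection from raw voltage, burst
# and network-burst detection, firing-rate summaries, and cross-correlogram
# synchrony (AUNCC).

#' Detect spikes from raw voltage traces
#'
#' Traces are band-passed 200-3000 Hz (unless `prefiltered`), the noise SD is
#' estimated robustly as `median(|v|) / 0.6745`, and events are timestamped
#' at threshold crossings of `threshold_mult` x SD (either polarity), keeping
#' at most one event per `dead_time_s` window.
#'
#' @param voltage electrodes x samples matrix for one well, or a list of such
#'   matrices (one per well).
#' @param fs sampling rate, Hz (default 12500).
#' @param threshold_mult multiple of the noise SD, default 5.
#' @param dead_time_s refractory window, s, default 1 ms.
#' @param prefiltered set TRUE when the traces are already band-passed.
#' @param duration recording length, s (defaults to `n_samples / fs`).
#' @return a `spike_train_set`.
#' @export
detect_spikes <- function(voltage, fs = 12500, threshold_mult = 5,
                          dead_time_s = 0.001, prefiltered = FALSE,
                          duration = NULL) {
  wells <- if (is.list(voltage)) voltage else list(well01 = voltage)
  if (is.null(names(wells))) names(wells) <- sprintf("well%02d", seq_along(wells))
  duration <- duration %||% (ncol(wells[[1]]) / fs)
  trains <- lapply(wells, function(v) {
    out <- lapply(seq_len(nrow(v)), function(e) {
      detect_spikes_trace(v[e, ], fs, threshold_mult, dead_time_s, prefiltered)
    })
    names(out) <- sprintf("e%02d", seq_len(nrow(v)))
    out
  })
  structure(list(spikes = trains, duration = duration,
                 n_electrodes_per_well = nrow(wells[[1]])),
            class = "spike_train_set")
}

detect_spikes_trace <- function(v, fs, threshold_mult, dead_time_s,
                                prefiltered) {
  if (sd(v) == 0) {
    warning("zero-variance trace: no spikes detected")
    return(numeric(0))
  }
  if (!prefiltered) v <- butter_bandpass(v, fs, c(200, 3000), order = 4)
  noise_sd <- median(abs(v)) / 0.6745
  thr <- threshold_mult * noise_sd
  above <- abs(v) >= thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(crossings)) return(numeric(0))
  dead <- round(dead_time_s * fs)
  keep <- crossings[1]
  last <- crossings[1]
  for (i in crossings[-1]) {
    if (i - last > dead) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1) / fs
}

#' Detect single-electrode bursts
#'
#' A burst is a maximal run of consecutive spikes in which every inter-spike
#' interval is at most `max_isi_s`; runs with at least `min_spikes` spikes
#' are emitted.
#'
#' @param train sorted spike times, s.
#' @param min_spikes minimum spikes per burst, default 5.
#' @param max_isi_s maximum within-burst ISI, s, default 0.100.
#' @return data.frame with `start_s`, `end_s`, `n_spikes` per burst.
#' @export
detect_bursts <- function(train, min_spikes = 5, max_isi_s = 0.100) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  n <- length(train)
  if (n == 0) return(empty)
  if (is.unsorted(train)) stop("spike train must be sorted")
  breaks <- which(diff(train) > max_isi_s)
  run_start <- c(1, breaks + 1)
  run_end <- c(breaks, n)
  len <- run_end - run_start + 1
  ok <- len >= min_spikes
  data.frame(start_s = train[run_start[ok]], end_s = train[run_end[ok]],
             n_spikes = as.integer(len[ok]))
}

#' Detect network bursts within a well
#'
#' Overlapping single-electrode bursts are merged into candidate windows
#' (union of overlapping burst intervals across the well); a window is a
#' network burst when the number of distinct participating electrodes is at
#' least `ceil(min_electrode_frac x n_active)` and the total number of spikes
#' inside the window (over all electrodes) is at least `min_total_spikes`.
#'
#' @param trains named list of sorted spike-time vectors (one per electrode).
#' @param active logical vector marking active electrodes (from
#'   [summarize_firing()]); bursts are taken from active electrodes.
#' @param min_total_spikes default 50.
#' @param min_electrode_frac default 0.35.
#' @param min_spikes,max_isi_s single-electrode burst parameters.
#' @return data.frame with `start_s`, `end_s`, `n_electrodes`, `total_spikes`.
#' @export
detect_network_bursts <- function(trains, active = NULL,
                                  min_total_spikes = 50,
                                  min_electrode_frac = 0.35,
                                  min_spikes = 5, max_isi_s = 0.100) {
  if (is.null(active)) active <- rep(TRUE, length(trains))
  n_active <- sum(active)
  if (n_active == 0) stop("no active electrodes")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_electrodes = integer(0), total_spikes = integer(0))
  bursts <- do.call(rbind, lapply(which(active), function(e) {
    b <- detect_bursts(trains[[e]], min_spikes, max_isi_s)
    if (nrow(b)) cbind(b, electrode = e) else NULL
  }))
  if (is.null(bursts) || nrow(bursts) == 0) return(empty)
  bursts <- bursts[order(bursts$start_s), ]
  # union of overlapping burst intervals
  grp <- integer(nrow(bursts))
  grp[1] <- 1L
  cur_end <- bursts$end_s[1]
  for (i in seq_len(nrow(bursts))[-1]) {
    if (bursts$start_s[i] <= cur_end) {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, bursts$end_s[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- bursts$end_s[i]
    }
  }
  need_elec <- ceiling(min_electrode_frac * n_active)
  out <- do.call(rbind, lapply(split(bursts, grp), function(b) {
    w0 <- min(b$start_s); w1 <- max(b$end_s)
    total <- sum(vapply(trains, function(tt) {
      sum(tt >= w0 & tt <= w1)
    }, numeric(1)))
    data.frame(start_s = w0, end_s = w1,
               n_electrodes = length(unique(b$electrode)),
               total_spikes = as.integer(total))
  }))
  out <- out[out$n_electrodes >= need_elec & out$total_spikes >= min_total_spikes, ]
  rownames(out) <- NULL
  out
}

#' Firing-rate and activity summaries for a well
#'
#' Mean firing rate (MFR) per electrode is spikes / duration; an electrode is
#' active at >= `active_rule_per_min` spikes per minute; the weighted mean
#' firing rate (wMFR) is, by default, the mean MFR over active electrodes
#' (vendor convention), with `wmfr_literal = TRUE` computing the literal
#' well-rate x active-electrode-count product instead.
#'
#' @param trains named list of spike-time vectors for one well.
#' @param duration recording length, s, default 1800.
#' @param active_rule_per_min activity threshold, spikes/min, default 5.
#' @param network_bursts optional result of [detect_network_bursts()] used
#'   for the network-burst frequency.
#' @param wmfr_literal use the literal product definition of wMFR.
#' @return a `well_metrics` list: `mfr`, `active`, `wmfr`,
#'   `network_burst_freq`.
#' @export
summarize_firing <- function(trains, duration = 1800, active_rule_per_min = 5,
                             network_bursts = NULL, wmfr_literal = FALSE) {
  if (duration <= 0) stop("duration must be positive")
  mfr <- vapply(trains, length, numeric(1)) / duration
  active <- mfr * 60 >= active_rule_per_min
  wmfr <- if (any(active)) {
    if (wmfr_literal) {
      (sum(mfr) / length(mfr)) * sum(active)
    } else {
      mean(mfr[active])
    }
  } else 0
  nbf <- if (is.null(network_bursts)) NA_real_ else nrow(network_bursts) / duration
  structure(list(mfr = mfr, active = active, wmfr = wmfr,
                 network_burst_freq = nbf),
            class = "well_metrics")
}

#' Area under the normalized cross-correlogram (AUNCC)
#'
#' Spike trains are binned at `bin_s`; for each electrode pair the
#' cross-correlogram is normalised by the geometric mean of the zero-lag
#' autocorrelations, `rho_xy(tau) = C_xy(tau) / sqrt(C_xx(0) C_yy(0))`, over
#' lags `|tau| <= max_lag_s`. AUNCC is the mean over pairs of the area
#' `sum(rho) * bin_s`; higher values indicate greater network synchrony.
#' The default lag window is a 10 ms synchrony window: the correlogram area
#' is invariant to spike-time jitter much smaller than the window, so the
#' window must be on the scale of the synchrony being measured for AUNCC to
#' decrease with desynchronisation.
#'
#' @param trains named list of spike-time vectors for one well (active
#'   electrodes).
#' @param duration recording length, s.
#' @param bin_s correlogram bin width, s, default 5 ms.
#' @param max_lag_s maximum lag, s, default 10 ms.
#' @return list with `auncc` and the pairwise normalized correlograms
#'   (`rho`, pairs x lags) and `lags_s`.
#' @export
compute_auncc <- function(trains, duration, bin_s = 0.005, max_lag_s = 0.010) {
  if (length(trains) < 2) stop("need at least 2 active electrodes")
  n_bins <- ceiling(duration / bin_s)
  counts <- t(vapply(trains, function(tt) {
    tabulate(pmin(n_bins, floor(tt / bin_s) + 1L), nbins = n_bins)
  }, numeric(n_bins)))
  n_e <- nrow(counts)
  max_lag <- round(max_lag_s / bin_s)
  lags <- -max_lag:max_lag
  auto0 <- rowSums(counts^2)
  if (any(auto0 == 0)) stop("empty spike train among active electrodes")
  pairs <- which(upper.tri(matrix(0, n_e, n_e)), arr.ind = TRUE)
  rho <- matrix(0, nrow(pairs), length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    if (tau >= 0) {
      a <- counts[, seq_len(n_bins - tau), drop = FALSE]
      b <- counts[, seq(1 + tau, n_bins), drop = FALSE]
    } else {
      a <- counts[, seq(1 - tau, n_bins), drop = FALSE]
      b <- counts[, seq_len(n_bins + tau), drop = FALSE]
    }
    C <- a %*% t(b)  # C[x, y] = sum_t x_t y_{t+tau}
    rho[, li] <- C[pairs] / sqrt(auto0[pairs[, 1]] * auto0[pairs[, 2]])
  }
  area <- rowSums(rho) * bin_s
  list(auncc = mean(area), rho = rho, lags_s = lags * bin_s,
       pair_area = area, pairs = pairs)
}
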
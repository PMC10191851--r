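# Speech-locked ECoG preprocessing: tumour-contact labelling, kurtosis-based
# channel screening, trial selection, epoching, high-gamma power (HGp) and
# event-related spectral perturbations (ERSP).

#' Construct a multichannel recording
#'
#' @param samples channels x time numeric matrix, signal units.
#' @param fs sampling rate, Hz.
#' @param channel_ids character labels, one per channel.
#' @param channel_coords n x 3 matrix of mm coordinates (may be NULL).
#' @param tissue_label per-channel label in `tumour`, `non_tumour`, `unknown`.
#' @return an object of class `recording`.
#' @export
new_recording <- function(samples, fs, channel_ids = NULL,
                          channel_coords = NULL, tissue_label = NULL) {
  samples <- as.matrix(samples)
  n_ch <- nrow(samples)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(n_ch))
  if (is.null(tissue_label)) tissue_label <- rep("unknown", n_ch)
  tissue_label <- match.arg(tissue_label, c("tumour", "non_tumour", "unknown"),
                            several.ok = TRUE)
  if (length(channel_ids) != n_ch || length(tissue_label) != n_ch) {
    stop("channel metadata length does not match channel count")
  }
  if (!is.null(channel_coords)) {
    channel_coords <- as.matrix(channel_coords)
    if (nrow(channel_coords) != n_ch || ncol(channel_coords) != 3 ||
        any(!is.finite(channel_coords))) {
      stop("channel_coords must be a finite n x 3 matrix")
    }
  }
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 channel_coords = channel_coords, tissue_label = tissue_label),
            class = "recording")
}

#' Label electrodes by distance to the tumour core
#'
#' An electrode is a tumour contact when its minimum Euclidean distance to any
#' point of the necrotic core geometry is at most `radius` (inclusive at the
#' boundary).
#'
#' @param channel_coords n x 3 matrix, mm.
#' @param tumour_core_geometry m x 3 matrix of core points, mm, same space.
#' @param radius mm, default 10.
#' @return data.frame with `distance_mm` and `tissue_label` per channel.
#' @export
label_electrodes <- function(channel_coords, tumour_core_geometry, radius = 10) {
  channel_coords <- as.matrix(channel_coords)
  tumour_core_geometry <- as.matrix(tumour_core_geometry)
  if (nrow(tumour_core_geometry) == 0) stop("empty tumour core geometry")
  if (ncol(channel_coords) != 3 || ncol(tumour_core_geometry) != 3) {
    stop("coordinates must have three columns (mm)")
  }
  d <- apply(channel_coords, 1, function(p) {
    sqrt(min(colSums((t(tumour_core_geometry) - p)^2)))
  })
  data.frame(distance_mm = d,
             tissue_label = ifelse(d <= radius, "tumour", "non_tumour"))
}

#' Reject channels with excessive kurtosis
#'
#' Channels whose sample kurtosis (Pearson convention, normal = 3) exceeds
#' `kurtosis_max` are removed; zero-variance channels are removed with reason
#' `"degenerate"` since their kurtosis is undefined.
#'
#' @param recording a [new_recording()].
#' @param kurtosis_max rejection threshold, default 5.0.
#' @return list with the screened `recording` and a `rejected` data.frame
#'   (channel id, kurtosis, reason).
#' @export
reject_noisy_channels <- function(recording, kurtosis_max = 5.0) {
  stopifnot(inherits(recording, "recording"))
  if (nrow(recording$samples) < 2) stop("need at least 2 channels")
  k <- apply(recording$samples, 1, sample_kurtosis)
  degenerate <- is.na(k)
  reject <- degenerate | (!is.na(k) & k > kurtosis_max)
  rejected <- data.frame(
    channel_id = recording$channel_ids[reject],
    kurtosis = k[reject],
    reason = ifelse(degenerate[reject], "degenerate", "kurtosis")
  )
  keep <- !reject
  out <- recording
  out$samples <- recording$samples[keep, , drop = FALSE]
  out$channel_ids <- recording$channel_ids[keep]
  out$tissue_label <- recording$tissue_label[keep]
  if (!is.null(recording$channel_coords)) {
    out$channel_coords <- recording$channel_coords[keep, , drop = FALSE]
  }
  list(recording = out, rejected = rejected, kurtosis = k)
}

#' Select analysable trials
#'
#' Keeps trials with a correct response and a stimulus-to-response latency of
#' at most `max_latency_s` (the rule excludes strictly greater delays).
#'
#' @param trials trial table with `correct` and `latency_s`.
#' @param max_latency_s seconds, default 2.
#' @return the filtered table, with a `rejections` attribute counting each
#'   rejection reason.
#' @export
select_trials <- function(trials, max_latency_s = 2.0) {
  assert_fields(trials, c("correct", "latency_s"), "trials")
  incorrect <- !trials$correct
  slow <- trials$latency_s > max_latency_s
  keep <- !incorrect & !slow
  out <- trials[keep, , drop = FALSE]
  attr(out, "rejections") <- c(incorrect = sum(incorrect),
                               slow = sum(slow & !incorrect))
  out
}

#' Epoch a recording around speech onsets
#'
#' Extracts half-open windows `[-2.0, +2.0)` s around each speech onset
#' (4 x fs samples; onset at sample index `2 * fs`, 0-based). Trials whose
#' window would cross a recording edge are dropped and logged.
#'
#' @param recording a [new_recording()].
#' @param trials selected trial table with `onset_s`.
#' @param window_s half-window length, s (default 2).
#' @return an `epoch_set`: `data` (trials x channels x time), `fs`, `window`,
#'   `trials` metadata; attribute `dropped` lists edge-dropped trial rows.
#' @export
epoch_speech_locked <- function(recording, trials, window_s = 2.0) {
  stopifnot(inherits(recording, "recording"))
  assert_fields(trials, "onset_s", "trials")
  fs <- recording$fs
  n_time <- ncol(recording$samples)
  half <- round(window_s * fs)
  onset_idx <- round(trials$onset_s * fs)  # 0-based sample of onset
  ok <- (onset_idx - half) >= 0 & (onset_idx + half) <= n_time
  dropped <- which(!ok)
  trials_ok <- trials[ok, , drop = FALSE]
  if (nrow(trials_ok) == 0) stop("no trials survive epoching")
  n_tr <- nrow(trials_ok)
  n_ch <- nrow(recording$samples)
  data <- array(NA_real_, c(n_tr, n_ch, 2 * half))
  for (i in seq_len(n_tr)) {
    idx <- (onset_idx[ok][i] - half + 1):(onset_idx[ok][i] + half)
    data[i, , ] <- recording$samples[, idx, drop = FALSE]
  }
  structure(list(data = data, fs = fs, window = c(-window_s, window_s),
                 trials = trials_ok, channel_ids = recording$channel_ids,
                 tissue_label = recording$tissue_label),
            class = "epoch_set", dropped = dropped)
}

#' High-gamma band power from speech-locked epochs
#'
#' Applies, in order: common-average reference (over the retained channels),
#' 0.1 Hz high-pass, 70-110 Hz FIR band-pass (300 designed taps, applied
#' forward-backward so the filter is zero phase), analytic-signal envelope,
#' and squaring. The result is nonnegative instantaneous high-gamma power.
#'
#' @param epochs an [epoch_speech_locked()] result.
#' @param band Hz pair, default `c(70, 110)`.
#' @param fir_order FIR design order, default 300.
#' @param reference `"car"` (common average, default) or `"none"`.
#' @param highpass_hz high-pass cutoff, Hz (default 0.1).
#' @return an `hgp_series`: `values` (trials x channels x time), `band`,
#'   `fs`, `provenance`.
#' @export
compute_hgp <- function(epochs, band = c(70, 110), fir_order = 300,
                        reference = c("car", "none"), highpass_hz = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"))
  reference <- match.arg(reference)
  fs <- epochs$fs
  if (band[2] >= fs / 2) stop("band edges must be below Nyquist")
  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_t <- dim(d)[3]
  values <- array(NA_real_, dim(d))
  for (tr in seq_len(n_tr)) {
    x <- matrix(d[tr, , ], n_ch, n_t)
    if (reference == "car" && n_ch > 1) {
      x <- sweep(x, 2, colMeans(x))
    }
    for (ch in seq_len(n_ch)) {
      y <- butter_highpass(x[ch, ], fs, highpass_hz)
      y <- fir_bandpass(y, fs, band, order = fir_order)
      values[tr, ch, ] <- Mod(analytic_signal(y))^2
    }
  }
  structure(list(values = values, band = band, fs = fs,
                 trials = epochs$trials, channel_ids = epochs$channel_ids,
                 tissue_label = epochs$tissue_label,
                 provenance = paste0(reference, " -> highpass ", highpass_hz,
                                     " Hz -> FIR ", band[1], "-", band[2],
                                     " Hz order ", fir_order,
                                     " (zero-phase) -> |analytic|^2")),
            class = "hgp_series")
}

#' Per-channel task-window HGp means
#'
#' Averages instantaneous HGp over a task window for each trial and channel,
#' then over trials, yielding one responsivity value per channel for group
#' statistics.
#'
#' @param hgp an `hgp_series` from [compute_hgp()].
#' @param window_s window relative to speech onset, s (default `c(0, 1)`).
#' @return data.frame with `channel_id`, `tissue_label`, `hgp_mean`.
#' @export
hgp_channel_means <- function(hgp, window_s = c(0, 1)) {
  stopifnot(inherits(hgp, "hgp_series"))
  n_t <- dim(hgp$values)[3]
  onset <- n_t / 2  # 0-based index of onset
  idx <- seq(floor(onset + window_s[1] * hgp$fs) + 1,
             min(n_t, ceiling(onset + window_s[2] * hgp$fs)))
  m <- apply(hgp$values[, , idx, drop = FALSE], 2, mean)
  data.frame(channel_id = hgp$channel_ids, tissue_label = hgp$tissue_label,
             hgp_mean = m)
}

#' Event-related spectral perturbations (z-scored high-gamma envelope)
#'
#' Processing chain on the continuous recording: downsample to 600 Hz,
#' 0.1 Hz high-pass, notch at 60 Hz and harmonics up to the post-downsample
#' Nyquist, 70-170 Hz band-pass with a Hamming-windowed sinc FIR filter,
#' analytic-signal envelope, 100 ms Gaussian smoothing, downsample to 100 Hz,
#' epoching around speech onset and z-scoring across each trial (per channel).
#'
#' @param recording a [new_recording()] (fs must be a multiple of 600).
#' @param trials selected trial table.
#' @param window_s epoch half-window, s.
#' @param out_fs output rate, Hz (default 100).
#' @return an `ersp_set`: `values` (trials x channels x time) at `out_fs`,
#'   with degenerate (zero-variance) trials flagged in `degenerate`.
#' @export
compute_ersp <- function(recording, trials, window_s = 2.0, out_fs = 100) {
  stopifnot(inherits(recording, "recording"))
  fs <- recording$fs
  if (fs %% 600 != 0) stop("recording fs must be an integer multiple of 600 Hz")
  x <- recording$samples
  n_ch <- nrow(x)

  fs1 <- 600
  env <- matrix(NA_real_, n_ch, ncol(x) / (fs / fs1))
  for (ch in seq_len(n_ch)) {
    y <- decimate_fir(x[ch, ], fs / fs1)
    y <- butter_highpass(y, fs1, 0.1)
    for (h in seq(60, fs1 / 2 - 30, by = 60)) {
      y <- butter_bandstop(y, fs1, c(h - 1, h + 1))
    }
    taps <- as.numeric(signal::fir1(300, c(70, 170) / (fs1 / 2),
                                    type = "pass"))  # Hamming-windowed sinc
    y <- signal::filtfilt(taps, 1, y)
    e <- Mod(analytic_signal(y))
    # 100 ms Gaussian kernel (FWHM), sd = 0.1 / 2.355 s
    sdk <- 0.1 / (2 * sqrt(2 * log(2))) * fs1
    kw <- round(4 * sdk)
    kern <- dnorm(seq(-kw, kw), sd = sdk)
    kern <- kern / sum(kern)
    pad <- c(rep(e[1], kw), e, rep(e[length(e)], kw))
    sm <- stats::filter(pad, kern, sides = 2)
    env[ch, ] <- sm[(kw + 1):(kw + length(e))]
  }
  step <- fs1 / out_fs
  env100 <- env[, seq(1, ncol(env), by = step), drop = FALSE]

  half <- round(window_s * out_fs)
  onset_idx <- round(trials$onset_s * out_fs)
  ok <- (onset_idx - half) >= 0 & (onset_idx + half) <= ncol(env100)
  trials_ok <- trials[ok, , drop = FALSE]
  if (nrow(trials_ok) == 0) stop("no trials survive epoching")
  n_tr <- nrow(trials_ok)
  values <- array(NA_real_, c(n_tr, n_ch, 2 * half))
  degenerate <- matrix(FALSE, n_tr, n_ch)
  for (i in seq_len(n_tr)) {
    idx <- (onset_idx[ok][i] - half + 1):(onset_idx[ok][i] + half)
    for (ch in seq_len(n_ch)) {
      seg <- env100[ch, idx]
      s <- sd(seg)
      if (!is.finite(s) || s == 0) {
        degenerate[i, ch] <- TRUE
        values[i, ch, ] <- NA_real_
      } else {
        values[i, ch, ] <- (seg - mean(seg)) / s
      }
    }
  }
  structure(list(values = values, fs = out_fs, window = c(-window_s, window_s),
                 trials = trials_ok, channel_ids = recording$channel_ids,
                 degenerate = degenerate),
            class = "ersp_set")
}
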
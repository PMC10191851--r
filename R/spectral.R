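# Multitaper spectral estimation (Thomson's method with Slepian tapers),
# Lorentzian aperiodic fitting in semi-log space, aperiodic-corrected gamma
# power, and the gamma-vs-HFC regression.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS of length `n` at time-bandwidth product `nw`,
#' unit-energy normalised, together with their band concentrations
#' (eigenvalues), evaluated by integrating each taper's spectrum over
#' `[-W, W]` on a zero-padded FFT grid.
#'
#' @param n taper length.
#' @param nw time-bandwidth product.
#' @param k number of tapers (`k <= 2 nw - 1` recommended).
#' @return list with `tapers` (n x k matrix) and `eigen` (length-k
#'   concentrations).
#' @export
dpss <- function(n, nw, k) {
  if (k > 2 * nw - 1 + 1e-9) {
    warning("k exceeds 2*NW - 1; trailing tapers are poorly concentrated")
  }
  h <- .dpss_tapers(as.integer(n), as.numeric(nw), as.integer(k))
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  # concentrations via zero-padded spectra
  nfft <- 2^ceiling(log2(4 * n))
  W <- nw / n
  pad <- rbind(h, matrix(0, nfft - n, k))
  H2 <- Mod(stats::mvfft(pad))^2
  f <- (seq_len(nfft) - 1) / nfft
  inband <- f <= W | f >= 1 - W
  eig <- colSums(H2[inband, , drop = FALSE]) / colSums(H2)
  list(tapers = h, eigen = eig)
}

#' Multitaper power spectral density (Thomson's method)
#'
#' Eigenvalue-weighted average of tapered periodograms using `n_tapers`
#' Slepian tapers at time-bandwidth `NW = (n_tapers + 1) / 2`, restricted to
#' `band`. The one-sided density integrates to the series variance.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param n_tapers number of Slepian tapers, default 29 (`NW = 15`).
#' @param band Hz pair to report, default `c(1, 50)`.
#' @return a `spectrum_estimate`: `freqs`, `psd` (one-sided density),
#'   `n_tapers`, `fs`.
#' @export
multitaper_psd <- function(series, fs, n_tapers = 29, band = c(1, 50)) {
  n <- length(series)
  if (n < 4 * fs) stop("series must be at least 4 s long")
  nw <- (n_tapers + 1) / 2
  dp <- dpss(n, nw, n_tapers)
  tapered <- dp$tapers * series  # recycles series down columns
  X <- stats::mvfft(tapered)
  P <- Mod(X)^2  # n x k
  S2 <- as.vector(P %*% dp$eigen) / sum(dp$eigen) / fs  # two-sided density
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  S1 <- S2[half]
  interior <- freqs[half] > 0 & freqs[half] < fs / 2
  S1[interior] <- 2 * S1[interior]
  keep <- freqs[half] >= band[1] & freqs[half] <= band[2]
  structure(list(freqs = freqs[half][keep], psd = S1[keep],
                 n_tapers = n_tapers, fs = fs),
            class = "spectrum_estimate")
}

#' Fit the Lorentzian aperiodic component in semi-log space
#'
#' Nonlinear least squares of `log10 PSD` against
#' `b - log10(k + f^chi)` with `k, chi >= 0`, in two passes: an initial fit,
#' masking of points more than 2.5 residual SD above the fit (oscillatory
#' peaks; the SD is estimated robustly via the median absolute deviation so
#' the peaks themselves do not inflate it), and a refit on the remaining
#' points. The mask-and-refit step is iterated until it stabilises.
#'
#' @param spectrum a `spectrum_estimate`.
#' @param peak_mask_sd residual threshold for the second pass, default 2.5.
#' @return an `aperiodic_fit`: `offset_b`, `knee_k`, `exponent_chi`,
#'   `fit_residual_rms`, `n_masked`, and `fitted(f)` evaluation via
#'   [aperiodic_curve()].
#' @export
fit_aperiodic <- function(spectrum, peak_mask_sd = 2.5) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  f <- spectrum$freqs
  y <- log10(spectrum$psd)
  if (length(f) < 20) stop("need at least 20 frequency points")

  nlfit <- function(ff, yy, w = rep(1, length(ff)), st = NULL) {
    if (is.null(st)) {
      i1 <- which.min(ff); i2 <- which.max(ff)
      chi0 <- max(0.1, (yy[i1] - yy[i2]) / (log10(ff[i2]) - log10(ff[i1])))
      st <- list(b = yy[i1] + log10(ff[i1]^chi0), k = 1e-3, chi = chi0)
    }
    dat <- data.frame(ff = ff, yy = yy, w = w)
    minpack.lm::nlsLM(yy ~ b - log10(k + ff^chi), data = dat, weights = w,
                      start = st, lower = c(-Inf, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  # pass 1: robust baseline on a log-spaced internal grid. Oscillatory peaks
  # occupy few octaves, so equal-weight-per-octave sampling plus an L1-type
  # IRLS loss anchors the fit on the aperiodic component.
  fg <- exp(seq(log(min(f)), log(max(f)), length.out = max(64, length(f))))
  yg <- stats::approx(f, y, xout = fg)$y
  fit <- tryCatch(nlfit(fg, yg), error = function(e) {
    stop("aperiodic fit did not converge: ", conditionMessage(e))
  })
  for (it in 1:5) {
    r <- yg - predict(fit)
    w <- 1 / pmax(abs(r), 1e-3)
    fit <- tryCatch(nlfit(fg, yg, w, as.list(coef(fit))),
                    error = function(e) fit)
  }
  # pass 2 (iterated): mask points more than peak_mask_sd robust SDs above
  # the baseline, refit unweighted on the remaining original grid points
  keep <- rep(TRUE, length(f))
  for (it in 1:2) {
    cf <- coef(fit)
    r <- y - (cf[["b"]] - log10(cf[["k"]] + f^cf[["chi"]]))
    s <- stats::mad(r)
    keep <- r <= peak_mask_sd * max(s, 1e-3)
    if (sum(keep) < 10) break
    fit <- tryCatch(nlfit(f[keep], y[keep], st = as.list(cf)),
                    error = function(e) fit)
  }
  cf <- coef(fit)
  curve_full <- cf[["b"]] - log10(cf[["k"]] + f^cf[["chi"]])
  structure(list(offset_b = cf[["b"]], knee_k = cf[["k"]],
                 exponent_chi = cf[["chi"]],
                 fit_residual_rms = sqrt(mean((y - curve_full)^2)),
                 n_masked = sum(!keep), freqs = f),
            class = "aperiodic_fit")
}

#' Evaluate a fitted aperiodic curve
#'
#' @param fit an `aperiodic_fit`.
#' @param f frequencies, Hz.
#' @return log10-power values of the aperiodic model at `f`.
#' @export
aperiodic_curve <- function(fit, f) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  fit$offset_b - log10(fit$knee_k + f^fit$exponent_chi)
}

#' Aperiodic-corrected band power
#'
#' Mean log10 residual of the spectrum above the fitted aperiodic component
#' over the band (default gamma, 30-50 Hz).
#'
#' @param spectrum a `spectrum_estimate`.
#' @param fit an `aperiodic_fit` for the same spectrum.
#' @param band Hz pair, default `c(30, 50)`.
#' @return scalar gamma power in log10 residual units.
#' @export
gamma_power <- function(spectrum, fit, band = c(30, 50)) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  idx <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  if (!any(idx)) stop("band outside spectrum range")
  mean(log10(spectrum$psd[idx]) - aperiodic_curve(fit, spectrum$freqs[idx]))
}

#' Regress per-subject gamma power on intratumoural HFC node counts
#'
#' @param gamma numeric vector, one aperiodic-corrected gamma value per
#'   subject.
#' @param hfc_counts matching vector of intratumoural HFC node counts.
#' @return a `regression_result` from [linear_regression()].
#' @export
regress_gamma_on_hfc <- function(gamma, hfc_counts) {
  linear_regression(hfc_counts, gamma)
}
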
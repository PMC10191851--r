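# Voxel-level functional connectivity: band-limited imaginary coherence,
# Fisher/standardised connectivity z-scores, contralesional-referenced voxel
# tests, tertile HFC/LFC classification and tumour HFC counting.

as_series_matrix <- function(series) {
  if (inherits(series, "voxel_series")) series$series else as.matrix(series)
}

# two-sample Welch t-test (Welch-Satterthwaite df); degenerate zero-variance
# samples with equal means give t = 0, p = 1 rather than an error
welch_t <- function(A, B) {
  nA <- length(A); nB <- length(B)
  vA <- var(A); vB <- var(B)
  d <- mean(A) - mean(B)
  se2 <- vA / nA + vB / nB
  if (se2 == 0) {
    return(c(t = if (d == 0) 0 else sign(d) * Inf,
             p = if (d == 0) 1 else 0))
  }
  tstat <- d / sqrt(se2)
  df <- se2^2 / (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  c(t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pairwise band-limited imaginary coherence
#'
#' Estimates segment-averaged cross-spectra (Hann-windowed Welch segments)
#' and returns, for every voxel pair, the magnitude of the imaginary part of
#' the coherency `C_xy(f) = S_xy / sqrt(S_xx S_yy)` averaged over the
#' frequency band. Imaginary coherence is insensitive to instantaneous
#' (zero-lag) real mixing, the signature of volume conduction.
#'
#' @param series a `voxel_series` or voxels x time matrix.
#' @param fs sampling rate (taken from the object when available).
#' @param band Hz pair, default the alpha band `c(8, 12)`.
#' @param segment_s Welch segment length, s.
#' @param overlap fractional segment overlap.
#' @return symmetric voxel x voxel matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
pairwise_imaginary_coherence <- function(series, fs = NULL, band = c(8, 12),
                                         segment_s = 1.0, overlap = 0.5) {
  x <- as_series_matrix(series)
  if (is.null(fs)) {
    if (!inherits(series, "voxel_series")) stop("fs required for plain matrices")
    fs <- series$fs
  }
  n_vox <- nrow(x)
  n_t <- ncol(x)
  L <- round(segment_s * fs)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n_t - L + 1, by = step)
  if (length(starts) < 20) stop("too few analysis segments (need >= 20)")
  if (any(apply(x, 1, sd) == 0)) stop("constant voxel series")

  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann
  freqs <- (seq_len(L) - 1) * fs / L
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("no frequency bins inside band")

  # per-bin tapered Fourier coefficients (voxels x segments), then the
  # cross-spectral matrix is one Hermitian matmul per bin
  Xb <- lapply(seq_along(bins), function(b) matrix(0 + 0i, n_vox, length(starts)))
  for (s in seq_along(starts)) {
    seg <- x[, starts[s]:(starts[s] + L - 1), drop = FALSE] *
      matrix(w, n_vox, L, byrow = TRUE)
    X <- stats::mvfft(t(seg))  # L x n_vox; rows = frequency bins
    for (b in seq_along(bins)) Xb[[b]][, s] <- X[bins[b], ]
  }
  ic <- matrix(0, n_vox, n_vox)
  for (b in seq_along(bins)) {
    S <- Xb[[b]] %*% Conj(t(Xb[[b]]))
    auto <- sqrt(Re(diag(S)))
    C <- S / outer(auto, auto)
    ic <- ic + abs(Im(C))
  }
  ic <- ic / length(bins)
  diag(ic) <- 0
  ic <- (ic + t(ic)) / 2
  if (inherits(series, "voxel_series")) {
    dimnames(ic) <- list(seq_len(n_vox), seq_len(n_vox))
  }
  ic
}

#' Standardised per-voxel mean connectivity ("Z-transformed connectivity")
#'
#' Fisher-transforms (atanh) each pairwise imaginary coherence, averages over
#' all other voxels per index voxel, then standardises to zero mean and unit
#' SD across voxels.
#'
#' @param ic_matrix symmetric IC matrix from
#'   [pairwise_imaginary_coherence()].
#' @return numeric vector of z-connectivity, one per voxel.
#' @export
voxel_connectivity_z <- function(ic_matrix) {
  n <- nrow(ic_matrix)
  if (n < 3) stop("need at least 3 voxels")
  if (any(ic_matrix >= 1)) {
    warning("IC values at 1 clipped to 1 - 1e-6 before atanh")
    ic_matrix[ic_matrix >= 1] <- 1 - 1e-6
  }
  z <- atanh(ic_matrix)
  diag(z) <- 0
  mean_z <- rowSums(z) / (n - 1)
  s <- sd(mean_z)
  if (s == 0) return(rep(0, n))
  (mean_z - mean(mean_z)) / s
}

#' Contralesional-referenced per-voxel connectivity test
#'
#' For each index voxel i, compares (two-tailed Welch t-test) the set of
#' Fisher-transformed IC values between i and a reference set of non-tumour
#' voxels against the per-reference-voxel means of the Fisher-transformed IC
#' between every voxel of the contralateral hemisphere and the same
#' reference set. Self-pairs are excluded on both sides.
#'
#' @param ic_matrix symmetric IC matrix.
#' @param hemisphere `"left"`/`"right"` per voxel.
#' @param non_tumour_voxel_set integer ids of the non-tumour reference set.
#' @param voxels index voxels to test (default all).
#' @return data.frame with `voxel`, `t_stat`, `p_value`, `p_fdr`.
#' @export
contralesional_test <- function(ic_matrix, hemisphere, non_tumour_voxel_set,
                                voxels = seq_len(nrow(ic_matrix))) {
  n <- nrow(ic_matrix)
  if (!length(non_tumour_voxel_set)) stop("non-tumour reference set is empty")
  stopifnot(length(hemisphere) == n)
  z <- atanh(pmin(ic_matrix, 1 - 1e-6))
  res <- data.frame(voxel = voxels, t_stat = NA_real_, p_value = NA_real_)
  for (h in c("left", "right")) {
    contra <- which(hemisphere != h)
    if (!length(contra)) stop("index voxel lacks a contralateral hemisphere")
    # per-reference-voxel mean over contralateral voxels, self-pairs removed
    zc <- z[contra, non_tumour_voxel_set, drop = FALSE]
    counts <- matrix(1, length(contra), length(non_tumour_voxel_set))
    self <- outer(contra, non_tumour_voxel_set, "==")
    zc[self] <- 0
    counts[self] <- 0
    B <- colSums(zc) / colSums(counts)
    for (i in voxels[hemisphere[voxels] == h]) {
      A <- z[i, setdiff(non_tumour_voxel_set, i)]
      w <- welch_t(A, B)
      res$t_stat[res$voxel == i] <- w[["t"]]
      res$p_value[res$voxel == i] <- w[["p"]]
    }
  }
  res$p_fdr <- p.adjust(res$p_value, method = "BH")
  res
}

#' Tertile classification of connectivity values
#'
#' Rank-based split of the z-connectivity values: the top `floor(n/3)` voxels
#' are HFC (high functional connectivity), the bottom `floor(n/3)` LFC, the
#' remainder intermediate. Ties are broken deterministically by voxel id.
#'
#' @param z_conn numeric vector of connectivity values.
#' @param voxel_ids ids used for deterministic tie-breaking (default
#'   positional).
#' @return factor with levels `LFC`, `intermediate`, `HFC`.
#' @export
classify_tertiles <- function(z_conn, voxel_ids = seq_along(z_conn)) {
  n <- length(z_conn)
  if (n < 3) stop("need at least 3 voxels")
  cls <- rep("intermediate", n)
  if (length(unique(z_conn)) == 1) {
    warning("constant connectivity vector; all voxels intermediate")
    return(factor(cls, levels = c("LFC", "intermediate", "HFC")))
  }
  k <- floor(n / 3)
  ord <- order(z_conn, voxel_ids)  # ascending; ties by id
  cls[ord[seq_len(k)]] <- "LFC"
  cls[ord[seq(n - k + 1, n)]] <- "HFC"
  factor(cls, levels = c("LFC", "intermediate", "HFC"))
}

#' Count HFC voxels inside an enhancing-tumour mask
#'
#' A tumour is HFC-positive when at least one HFC-class voxel lies inside the
#' contrast-enhancing mask.
#'
#' @param conn_class factor from [classify_tertiles()].
#' @param enhancing_tumour_mask logical vector on the same voxel grid.
#' @return list with `hfc_voxel_count` and `hfc_positive`.
#' @export
count_hfc_in_tumour <- function(conn_class, enhancing_tumour_mask) {
  if (!any(enhancing_tumour_mask)) stop("empty tumour mask")
  stopifnot(length(conn_class) == length(enhancing_tumour_mask))
  n <- sum(conn_class == "HFC" & enhancing_tumour_mask)
  list(hfc_voxel_count = n, hfc_positive = n >= 1)
}

#' Full connectivity map for a voxel series
#'
#' Convenience wrapper running IC, z-connectivity, the contralesional test
#' and tertile classification.
#'
#' @param series a `voxel_series`.
#' @param band,segment_s,overlap passed to
#'   [pairwise_imaginary_coherence()].
#' @return a `connectivity_map`: data.frame per voxel (`mean_ic`, `z_conn`,
#'   `t_stat`, `p_value`, `p_fdr`, `conn_class`) plus the IC matrix.
#' @export
connectivity_map <- function(series, band = c(8, 12), segment_s = 1,
                             overlap = 0.5) {
  stopifnot(inherits(series, "voxel_series"))
  ic <- pairwise_imaginary_coherence(series, band = band,
                                     segment_s = segment_s, overlap = overlap)
  z <- voxel_connectivity_z(ic)
  ref <- which(!series$tumour_mask)
  ct <- contralesional_test(ic, series$hemisphere, ref)
  cls <- classify_tertiles(z)
  map <- data.frame(voxel = seq_len(nrow(ic)),
                    mean_ic = rowSums(ic) / (nrow(ic) - 1),
                    z_conn = z, t_stat = ct$t_stat, p_value = ct$p_value,
                    p_fdr = ct$p_fdr, conn_class = cls)
  structure(list(map = map, ic = ic, series_meta = series[c(
    "grid_index", "spacing", "hemisphere", "mirror_pair", "tumour_mask")]),
    class = "connectivity_map")
}
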
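# Shared numerical helpers: seeded stream splitting, analytic signal,
# zero-phase filtering chains used by both the ECoG and simulation stages.

#' Split a master seed into independent sub-stream seeds
#'
#' Deterministically derives `n` sub-seeds from one master seed so that each
#' participant/well/voxel owns its own random stream: regenerating with a
#' larger `n` leaves the first streams untouched.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
split_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Analytic signal via the one-sided Fourier construction
#'
#' Returns the complex analytic signal whose real part is the input and whose
#' modulus is the instantaneous envelope (the Hilbert-transform envelope).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(as.complex(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# zero-phase FIR bandpass: `order` designed taps (fir1, Hamming window by
# default) applied forward-backward
fir_bandpass <- function(x, fs, band, order = 300) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band edge at or above Nyquist (", ny, " Hz)")
  taps <- as.numeric(signal::fir1(order, band / ny, type = "pass"))
  signal::filtfilt(taps, 1, x)
}

# zero-phase Butterworth high-pass; at very low cutoffs a first-order design
# keeps the recursion numerically stable
butter_highpass <- function(x, fs, cutoff, order = 1) {
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  signal::filtfilt(bt, x)
}

butter_bandstop <- function(x, fs, band, order = 2) {
  bt <- signal::butter(order, band / (fs / 2), type = "stop")
  signal::filtfilt(bt, x)
}

butter_bandpass <- function(x, fs, band, order = 4) {
  bt <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bt, x)
}

# integer-factor decimation with zero-phase FIR anti-alias lowpass
decimate_fir <- function(x, factor, order = 120) {
  if (factor == 1) return(x)
  taps <- as.numeric(signal::fir1(order, 0.8 / factor, type = "low"))
  y <- signal::filtfilt(taps, 1, x)
  y[seq(1, length(y), by = factor)]
}

# sample kurtosis, Pearson convention (normal -> 3)
sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fields <- function(x, fields, what) {
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    stop(what, " is missing field(s): ", paste(missing, collapse = ", "))
  }
}
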
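# Shared fixtures, all built in code.

# two-class feature matrix with class means separated by `sep` noise SDs on
# every feature, grouped by participant
make_features <- function(sep, n_part = 10, n_trials = 20, n_feat = 10,
                          seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_part), function(p) {
    lab <- rep(c("low_freq_word", "high_freq_word"), n_trials / 2)
    X <- matrix(rnorm(n_trials * n_feat), n_trials, n_feat) +
      outer(ifelse(lab == "low_freq_word", -sep / 2, sep / 2), rep(1, n_feat))
    colnames(X) <- paste0("f", seq_len(n_feat))
    cbind(data.frame(group = p, label = lab), as.data.frame(X))
  }))
}

# channel-level HGp table from the mixed-model generating process
make_lme_table <- function(effect, seed, n_part = 14, n_chan = 40,
                           part_sd = 0.5, resid_sd = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_part), function(p) {
    b <- rnorm(1, 0, part_sd)
    tis <- rep(c("tumour", "non_tumour"), each = n_chan / 2)
    data.frame(participant = p, tissue_label = tis,
               hgp = b + ifelse(tis == "tumour", effect, 0) +
                 rnorm(n_chan, 0, resid_sd))
  }))
}

# brute-force Benjamini-Hochberg step-up from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in seq(m, 1)) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

# exhaustive-scan burst oracle: every maximal run with all ISIs <= max_isi
# and length >= min_spikes
burst_oracle <- function(train, min_spikes = 5, max_isi = 0.1) {
  n <- length(train)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (train[j + 1] - train[j]) <= max_isi) j <- j + 1
    if (j - i + 1 >= min_spikes) {
      out <- rbind(out, data.frame(start_s = train[i], end_s = train[j],
                                   n_spikes = as.integer(j - i + 1)))
    }
    i <- j + 1
  }
  if (is.null(out)) {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  }
  out
}

# n_copies of a base train with Gaussian jitter (independent per electrode)
jittered_trains <- function(base, jitter_sd, n_copies = 8) {
  tr <- lapply(seq_len(n_copies), function(i) {
    sort(pmax(0, base + rnorm(length(base), sd = jitter_sd)))
  })
  names(tr) <- sprintf("e%02d", seq_len(n_copies))
  tr
}

# minimal EDF writer (fixed-layout header + 16-bit records) used to exercise
# the EDF importer against independently constructed bytes
write_edf_fixture <- function(path, samples, fs, phys_range = c(-200, 200)) {
  ns <- nrow(samples)
  spr <- fs  # one-second records
  n_rec <- ncol(samples) / spr
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("synthetic recording", 80), pad("01.01.20", 8),
                pad("00.00.00", 8), pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_rec, 8), pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) paste0(vapply(vals, pad, character(1), w = w),
                                  collapse = "")
  dig <- c(-32768, 32767)
  sig <- paste0(fld(sprintf("ch%d", seq_len(ns)), 16), fld(rep("", ns), 80),
                fld(rep("uV", ns), 8), fld(rep(phys_range[1], ns), 8),
                fld(rep(phys_range[2], ns), 8), fld(rep(dig[1], ns), 8),
                fld(rep(dig[2], ns), 8), fld(rep("", ns), 80),
                fld(rep(spr, ns), 8), fld(rep("", ns), 32))
  writeChar(sig, con, eos = NULL)
  gain <- diff(phys_range) / diff(dig)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    block <- vapply(seq_len(ns), function(s) {
      as.integer(round((samples[s, idx] - phys_range[1]) / gain + dig[1]))
    }, integer(spr))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}
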
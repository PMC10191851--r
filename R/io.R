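# File formats: versioned binary container for recordings/voxel series,
# minimal EDF import, CSV tables, NIfTI connectivity maps and masks.

CONTAINER_VERSION <- 1L

#' Write a signal object to the package's binary container
#'
#' Serialises a `recording`, `voxel_series`, `spike_train_set` or
#' `connectivity_map` with a format header so that reads are validated; the
#' round trip reproduces all arrays bit-exactly.
#'
#' @param object the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(object, path) {
  ok <- c("recording", "voxel_series", "spike_train_set", "connectivity_map")
  cls <- intersect(class(object), ok)
  if (!length(cls)) stop("unsupported object class: ", class(object)[1])
  saveRDS(list(format = "gliocircuit-container",
               version = CONTAINER_VERSION,
               class = cls[1], payload = object),
          path)
  invisible(path)
}

#' Read a signal object written by [write_container()]
#'
#' @param path file path.
#' @return the stored object.
#' @export
read_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("malformed or truncated container file '", path, "': ",
         conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "gliocircuit-container")) {
    stop("file '", path, "' is not a gliocircuit container")
  }
  if (obj$version > CONTAINER_VERSION) {
    stop("container version ", obj$version, " is newer than supported")
  }
  obj$payload
}

#' Import a recording from an EDF file
#'
#' Minimal reader for the European Data Format (EDF): parses the fixed-layout
#' ASCII header and the 16-bit little-endian data records, applying the
#' per-channel physical calibration. All channels must share one sampling
#' rate. Annotation channels are not supported.
#'
#' @param path path to an EDF file.
#' @return a `recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop("malformed EDF: truncated header")
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(field(hdr, 237, 8))
  record_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count")
  sig_hdr <- readChar(con, ns * 256, useBytes = TRUE)
  if (nchar(sig_hdr) < ns * 256) stop("malformed EDF: truncated signal header")
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
  }
  labels <- take(16, 0)
  phys_min <- as.numeric(take(8, ns * (16 + 80 + 8)))
  phys_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8)))
  dig_min <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  n_samp_rec <- as.integer(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  if (length(unique(n_samp_rec)) != 1) {
    stop("EDF channels with differing sampling rates are not supported")
  }
  spr <- n_samp_rec[1]
  fs <- spr / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- matrix(NA_real_, ns, n_records * spr)
  for (r in seq_len(n_records)) {
    raw <- readBin(con, "integer", n = ns * spr, size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < ns * spr) stop("malformed EDF: truncated data record")
    block <- matrix(raw, nrow = spr)
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      samples[s, idx] <- phys_min[s] + gain[s] * (block[, s] - dig_min[s])
    }
  }
  new_recording(samples, fs, channel_ids = labels)
}

#' Write a connectivity map to NIfTI volumes and a tidy CSV
#'
#' Emits one NIfTI volume per field (`mean_ic`, `z_conn`, `t_stat`,
#' `p_value`, class codes LFC=0 / intermediate=1 / HFC=2) on the voxel grid
#' with the grid spacing in the header, plus `<prefix>_map.csv`.
#'
#' @param cmap a `connectivity_map`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_connectivity_nifti <- function(cmap, prefix) {
  stopifnot(inherits(cmap, "connectivity_map"))
  gi <- cmap$series_meta$grid_index
  sp <- cmap$series_meta$spacing
  off <- apply(gi, 2, min)
  dims <- apply(gi, 2, max) - off + 1
  files <- character(0)
  fields <- list(mean_ic = cmap$map$mean_ic, z_conn = cmap$map$z_conn,
                 t_stat = cmap$map$t_stat, p_value = cmap$map$p_value,
                 conn_class = as.integer(cmap$map$conn_class) - 1L)
  for (nm in names(fields)) {
    arr <- array(NA_real_, dims)
    arr[cbind(gi[, 1] - off[1] + 1, gi[, 2] - off[2] + 1,
              gi[, 3] - off[3] + 1)] <- fields[[nm]]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(sp, 3)
    f <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  csv <- paste0(prefix, "_map.csv")
  write.csv(cmap$map, csv, row.names = FALSE)
  invisible(c(files, csv))
}

#' Read a voxel mask from NIfTI
#'
#' @param path NIfTI file path.
#' @param grid_index voxels x 3 grid indices to extract (same layout the
#'   connectivity writer uses).
#' @return logical vector, one entry per voxel.
#' @export
read_mask_nifti <- function(path, grid_index) {
  img <- RNifti::readNifti(path)
  off <- apply(grid_index, 2, min)
  idx <- cbind(grid_index[, 1] - off[1] + 1, grid_index[, 2] - off[2] + 1,
               grid_index[, 3] - off[3] + 1)
  as.logical(img[idx] != 0)
}

#' Write spike trains as a tidy CSV (well, electrode, time_s)
#'
#' @param spikes a `spike_train_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  rows <- do.call(rbind, lapply(names(spikes$spikes), function(w) {
    well <- spikes$spikes[[w]]
    do.call(rbind, lapply(names(well), function(e) {
      if (!length(well[[e]])) return(NULL)
      data.frame(well = w, electrode = e, time_s = well[[e]])
    }))
  }))
  if (is.null(rows)) {
    rows <- data.frame(well = character(0), electrode = character(0),
                       time_s = numeric(0))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from the CSV layout of [write_spike_csv()]
#'
#' @param path CSV path.
#' @param duration recording length, s.
#' @param n_electrodes_per_well electrodes per well (silent electrodes are
#'   restored as empty trains).
#' @return a `spike_train_set`.
#' @export
read_spike_csv <- function(path, duration, n_electrodes_per_well = 16) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_fields(df, c("well", "electrode", "time_s"), "spike table")
  wells <- lapply(split(df, df$well), function(wd) {
    trains <- lapply(sprintf("e%02d", seq_len(n_electrodes_per_well)),
                     function(e) sort(wd$time_s[wd$electrode == e]))
    names(trains) <- sprintf("e%02d", seq_len(n_electrodes_per_well))
    trains
  })
  structure(list(spikes = wells, duration = duration,
                 n_electrodes_per_well = n_electrodes_per_well),
            class = "spike_train_set")
}
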
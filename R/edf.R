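# Minimal European Data Format (EDF, 16-bit) reader and writer.
#
# EDF is a fixed-layout ASCII header (256 bytes + 256 per signal) followed by
# data records of little-endian int16 samples, channel-blocked within each
# record. Physical values are recovered by the linear digital->physical map
# declared per signal. Only plain EDF is handled (no EDF+ annotations).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- ifelse(nchar(x) > width, substr(x, 1L, width), x)
  formatC(x, width = -width)  # left-justified, space padded
}

.aux_pattern <- "^(ECG|EKG|EMG|EOG|AUX|STATUS|MARKER)"

#' Write an epoch set to an EDF file
#'
#' Epochs are written back-to-back as one continuous recording, one data
#' record per epoch. Samples are quantized to the 16-bit digital range with a
#' per-channel physical scale, so the round-trip error is bounded by half a
#' quantization step (`(max - min) / 65535 / 2` per channel).
#'
#' @param epochs An [eeg_epochs] object.
#' @param path Output file path.
#' @param physical_dim Physical dimension string written per signal.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(epochs, path, physical_dim = "uV") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  ns <- d[2L]
  spr <- d[3L]               # samples per record = samples per epoch
  n_rec <- d[1L]
  dur <- spr / epochs$fs
  pmin <- apply(epochs$data, 2L, min)
  pmax <- apply(epochs$data, 2L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    .edf_pad("0", 8),
    .edf_pad(ifelse(is.na(epochs$subject_id), "X", epochs$subject_id), 80),
    .edf_pad(ifelse(is.na(epochs$session), "X", epochs$session), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(hdr_bytes, 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(format(dur, digits = 8), 8),
    .edf_pad(ns, 4),
    paste(.edf_pad(epochs$channel_labels, 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(physical_dim, 8), ns), collapse = ""),
    paste(.edf_pad(format(pmin, digits = 7), 8), collapse = ""),
    paste(.edf_pad(format(pmax, digits = 7), 8), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    m <- epoch_matrix(epochs, r)                    # channels x samples
    dig <- round((m - pmin) / scale + dmin)
    dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf_header <- function(con, path) {
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < n)
      stopf("malformed EDF header in '%s': truncated file", path)
    trimws(raw)
  }
  version <- rd(8L)
  patient <- rd(80L); recording <- rd(80L)
  rd(8L); rd(8L)                                    # date, time
  hdr_bytes <- suppressWarnings(as.integer(rd(8L)))
  rd(44L)
  n_rec <- suppressWarnings(as.integer(rd(8L)))
  dur <- suppressWarnings(as.numeric(rd(8L)))
  ns <- suppressWarnings(as.integer(rd(4L)))
  if (anyNA(c(hdr_bytes, n_rec, dur, ns)) || ns < 1L)
    stopf("malformed EDF header in '%s'", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16L); fld(80L); dim_ <- fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L)); fld(32L)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stopf("malformed EDF signal headers in '%s'", path)
  list(patient = patient, recording = recording, n_rec = n_rec, dur = dur,
       ns = ns, labels = labels, dim = dim_, pmin = pmin, pmax = pmax,
       dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF file into an epoch set
#'
#' Signals are converted to physical units via the per-signal linear map.
#' Channel labels are normalized ([normalize_channel_labels()]); non-EEG
#' polygraphy channels (labels starting with ECG/EKG/EMG/EOG/AUX) are split
#' out and returned in the `"aux"` attribute as a separate [eeg_epochs].
#'
#' @param path Path to an EDF file.
#' @param epoch_seconds Epoch length for re-segmentation; the default `NULL`
#'   uses the file's data-record duration (the writer emits one record per
#'   epoch, so round trips preserve epoching).
#' @param montage Optional [montage()] to check coverage against; missing
#'   scalp channels trigger a warning listing them.
#' @return An [eeg_epochs] of the scalp channels, with attribute `"aux"`
#'   (an `eeg_epochs` of auxiliary channels, or `NULL`).
#' @export
read_edf <- function(path, epoch_seconds = NULL, montage = NULL) {
  if (!file.exists(path) || file.size(path) < 256)
    stopf("'%s' is not a valid EDF file (missing or too short)", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_edf_header(con, path)
  if (any(h$spr < 1L) || h$n_rec < 0L || h$dur <= 0)
    stopf("malformed EDF header in '%s'", path)

  n_per_rec <- sum(h$spr)
  raw <- readBin(con, "integer", n = n_per_rec * h$n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_per_rec * h$n_rec)
    stopf("EDF data truncated in '%s'", path)

  if (length(unique(h$spr)) != 1L)
    stopf("mixed per-signal sampling rates in '%s' are not supported", path)
  spr <- h$spr[1L]
  fs <- spr / h$dur

  # records x (ns * spr) -> channels x total samples
  rec <- matrix(raw, nrow = n_per_rec, ncol = h$n_rec)
  sig <- matrix(0, nrow = h$ns, ncol = spr * h$n_rec)
  for (s in seq_len(h$ns)) {
    rows <- ((s - 1L) * spr + 1L):(s * spr)
    sig[s, ] <- as.numeric(rec[rows, ])
  }
  scale <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  sig <- (sig - h$dmin) * scale + h$pmin

  labels <- normalize_channel_labels(h$labels)
  is_aux <- grepl(.aux_pattern, toupper(labels))

  if (is.null(epoch_seconds)) epoch_seconds <- h$dur
  len <- round(epoch_seconds * fs)
  n_ep <- floor(ncol(sig) / len)
  if (n_ep < 1L) stopf("recording shorter than one epoch")
  to_epochs <- function(mat, labs, session) {
    arr <- array(0, c(n_ep, nrow(mat), len))
    for (e in seq_len(n_ep))
      arr[e, , ] <- mat[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
    eeg_epochs(arr, fs = fs, channel_labels = labs,
               subject_id = h$patient, session = session)
  }
  session <- if (h$recording %in% c("pre", "post")) h$recording
             else NA_character_
  out <- to_epochs(sig[!is_aux, , drop = FALSE], labels[!is_aux], session)
  attr(out, "aux") <- if (any(is_aux))
    to_epochs(sig[is_aux, , drop = FALSE], labels[is_aux], session)

  if (!is.null(montage)) {
    missing <- setdiff(montage$labels, out$channel_labels)
    if (length(missing))
      warnf("montage mismatch: %d scalp channel(s) absent from '%s': %s",
            length(missing), basename(path), paste(missing, collapse = ", "))
  }
  out
}
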
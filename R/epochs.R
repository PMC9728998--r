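# EpochSet container: epochs x channels x samples of EEG voltage.

#' Construct an EEG epoch set
#'
#' The unit container of the package: a 3-d numeric array of voltages
#' (microvolts) indexed epoch x channel x sample, with sampling rate, channel
#' labels and session metadata. Epochs are fixed-length artifact-free segments
#' (the reference acquisition uses 20 epochs of 8 s = 8,192 samples at
#' 1,024 Hz on 61 scalp channels).
#'
#' @param data Numeric array `(n_epochs, n_channels, n_samples)`. A matrix is
#'   taken as a single epoch `(channels x samples)`.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id Optional subject identifier.
#' @param session Optional session tag, `"pre"` or `"post"`.
#' @return An object of class `eeg_epochs`.
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 3 * 100), c(2, 3, 100)), fs = 100,
#'                 channel_labels = c("Fz", "Cz", "Pz"))
#' x
#' @export
eeg_epochs <- function(data, fs, channel_labels,
                       subject_id = NA_character_,
                       session = NA_character_) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!(is.array(data) && length(dim(data)) == 3L))
    stopf("`data` must be a 3-d array (epoch x channel x sample)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("`fs` must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(data)[2L])
    stopf("channel count (%d) does not match label count (%d)",
          dim(data)[2L], length(channel_labels))
  if (anyDuplicated(channel_labels))
    stopf("duplicate channel labels")
  if (!is.na(session) && !session %in% c("pre", "post"))
    stopf("`session` must be \"pre\" or \"post\"")
  dimnames(data) <- list(NULL, channel_labels, NULL)
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, session = session),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d epoch(s) x %d channel(s) x %d sample(s) @ %g Hz (%.3g s)\n",
    d[1L], d[2L], d[3L], x$fs, d[3L] / x$fs))
  if (!is.na(x$subject_id) || !is.na(x$session))
    cat(sprintf("  subject: %s  session: %s\n", x$subject_id, x$session))
  invisible(x)
}

#' @rdname eeg_epochs
#' @param x An `eeg_epochs` object.
#' @export
n_epochs <- function(x) dim(x$data)[1L]

#' @rdname eeg_epochs
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname eeg_epochs
#' @export
n_samples <- function(x) dim(x$data)[3L]

# one epoch as a channels x samples matrix
epoch_matrix <- function(x, i) {
  m <- x$data[i, , , drop = FALSE]
  dim(m) <- dim(x$data)[2:3]
  rownames(m) <- x$channel_labels
  m
}

# replace data keeping metadata
replace_data <- function(x, data) {
  dimnames(data) <- list(NULL, x$channel_labels, NULL)
  x$data <- data
  x
}
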
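# Preprocessing: common-average reference and the frequency-domain band
# filter bank (raised-cosine transitions, zero phase).

#' Canonical EEG frequency bands
#'
#' The five rhythms with their passbands and transition widths:
#' delta 0.5-3 Hz (transitions 1 / 2 Hz on the low / high side),
#' theta 3-8 Hz (2 / 3), alpha 8-12 Hz (3 / 4), beta 12-30 Hz (4 / 5),
#' gamma 30-50 Hz (3 / 3). Transition bands extend outward from the stated
#' cut-offs, so the printed passband is passed at unit gain; the delta low
#' transition is clamped at 0 Hz.
#'
#' @param name Optional band name; default returns all five.
#' @return A data frame with columns `name`, `low`, `high`,
#'   `transition_low`, `transition_high` (Hz).
#' @examples
#' band_definitions()
#' @export
band_definitions <- function(name = NULL) {
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0.5, 3, 8, 12, 30),
    high = c(3, 8, 12, 30, 50),
    transition_low = c(1, 2, 3, 4, 3),
    transition_high = c(2, 3, 4, 5, 3),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(bands)
  if (!all(name %in% bands$name))
    stopf("unknown band name(s): %s",
          paste(setdiff(name, bands$name), collapse = ", "))
  bands[match(name, bands$name), , drop = FALSE]
}

.band_names <- c("delta", "theta", "alpha", "beta", "gamma")

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample of every epoch, the instantaneous mean across
#' all channels, so each sample's channel mean becomes zero. The operation is
#' idempotent.
#'
#' @param epochs An [eeg_epochs] object.
#' @param expected_channels Number of scalp channels the montage expects
#'   (default 61). Use `NULL` to skip the check (explicit override).
#' @return An `eeg_epochs` with zero instantaneous channel mean.
#' @export
common_average_reference <- function(epochs, expected_channels = 61L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.null(expected_channels) && n_channels(epochs) != expected_channels)
    stopf(paste0("common average expects %d channels, got %d ",
                 "(pass expected_channels = NULL to override)"),
          expected_channels, n_channels(epochs))
  m <- apply(epochs$data, c(1L, 3L), mean)          # epoch x sample means
  d <- epochs$data - aperm(array(m, c(dim(m), dim(epochs$data)[2L])),
                           c(1L, 3L, 2L))
  replace_data(epochs, d)
}

#' Magnitude response of a band filter on the DFT grid
#'
#' Unit gain inside the passband, zero beyond passband +/- transition width,
#' raised-cosine roll-off across each transition (so the midpoint of a
#' transition has gain 0.5). The response is even in frequency, suitable for
#' zero-phase multiplication of a real signal's spectrum.
#'
#' @param band One row of [band_definitions()] (or a list with fields `low`,
#'   `high`, `transition_low`, `transition_high`).
#' @param n_samples Epoch length in samples.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`: gains on the full (two-sided)
#'   DFT frequency grid `(0, fs/n, ..., -fs/n)`.
#' @export
band_filter_response <- function(band, n_samples, fs) {
  lo <- band$low; hi <- band$high
  wlo <- band$transition_low; whi <- band$transition_high
  if (!(0 < lo && lo < hi && hi <= fs / 2))
    stopf("passband [%g, %g] Hz must lie inside (0, %g]", lo, hi, fs / 2)
  if (hi + whi > fs / 2)
    stopf("high transition (%g + %g Hz) extends above Nyquist (%g Hz)",
          hi, whi, fs / 2)
  stop_lo <- lo - wlo
  if (stop_lo < 0) {
    if (lo > 1)  # clamping is reserved for near-DC bands like delta
      stopf("low transition (%g - %g Hz) extends below 0 Hz", lo, wlo)
    stop_lo <- 0
    wlo <- lo
  }
  f <- (0:(n_samples - 1L)) * fs / n_samples
  f <- pmin(f, fs - f)                              # fold: two-sided grid
  g <- numeric(n_samples)
  g[f >= lo & f <= hi] <- 1
  ramp_up <- f > stop_lo & f < lo
  if (wlo > 0)
    g[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - stop_lo) / wlo))
  ramp_dn <- f > hi & f < hi + whi
  g[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - hi) / whi))
  g
}

# zero-phase filter a channels x samples matrix by spectral multiplication
.filter_matrix <- function(m, gain) {
  n <- ncol(m)
  sp <- t(stats::mvfft(t(m)))
  Re(t(stats::mvfft(t(sp * rep(gain, each = nrow(m))), inverse = TRUE))) / n
}

#' Apply a zero-phase band filter to an epoch set
#'
#' Each epoch is (optionally) demeaned, transformed to the frequency domain,
#' multiplied by the real [band_filter_response()], and inverse-transformed;
#' the result has the same length and no phase distortion. Epochs are
#' filtered independently (they are non-contiguous selections).
#'
#' @param epochs An [eeg_epochs] object (finite values).
#' @param band A band definition row, or a band name string.
#' @param demean Remove each channel's epoch mean first (default `TRUE`).
#' @return Filtered `eeg_epochs` of identical shape.
#' @export
apply_band_filter <- function(epochs, band, demean = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.character(band)) band <- band_definitions(band)
  if (!all(is.finite(epochs$data))) stopf("epochs contain non-finite values")
  gain <- band_filter_response(band, n_samples(epochs), epochs$fs)
  d <- epochs$data
  for (e in seq_len(dim(d)[1L])) {
    m <- epoch_matrix(epochs, e)
    if (demean) m <- m - rowMeans(m)
    d[e, , ] <- .filter_matrix(m, gain)
  }
  replace_data(epochs, d)
}

#' Common-average reference then decompose into the five canonical bands
#'
#' Order of operations is fixed: re-reference first, then filter each band.
#'
#' @param epochs An [eeg_epochs] object.
#' @param expected_channels Passed to [common_average_reference()].
#' @return Named list of five `eeg_epochs` (delta, theta, alpha, beta, gamma),
#'   each the same shape as the input, with attribute `"broadband"` holding
#'   the re-referenced unfiltered epochs used for aperiodic fitting.
#' @export
extract_band_stack <- function(epochs, expected_channels = 61L) {
  ref <- common_average_reference(epochs, expected_channels)
  bands <- band_definitions()
  out <- lapply(seq_len(nrow(bands)), function(i)
    apply_band_filter(ref, bands[i, , drop = FALSE]))
  names(out) <- bands$name
  attr(out, "broadband") <- ref
  out
}
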
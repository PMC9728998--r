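# Aperiodic (1/f^chi) spectral parameterization.
#
# The aperiodic component of an EEG spectrum follows P(f) ~ 10^offset / f^chi:
# in log-log coordinates a straight line with intercept `offset` (log10 power
# at 1 Hz) and slope -chi. Oscillatory peaks ride on top of the line; the fit
# excludes them iteratively.

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hamming windows. One-sided density
#' scaling: the integral of the density over frequency equals the series
#' variance (Parseval, up to the window taper correction).
#'
#' @param series Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param window_seconds Segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution).
#' @param overlap_fraction Segment overlap (default 0.5). An 8-s epoch with
#'   2-s windows at 50\% overlap yields 7 segments.
#' @param demean Remove the series mean first (default `TRUE`).
#' @return Object of class `spectrum_psd`: list with `freqs` (Hz, strictly
#'   increasing) and `power` (uV^2/Hz).
#' @export
welch_psd <- function(series, fs, window_seconds = 2, overlap_fraction = 0.5,
                      demean = TRUE) {
  nwin <- round(window_seconds * fs)
  n <- length(series)
  if (nwin > n) stopf("window (%d samples) longer than series (%d)", nwin, n)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stopf("overlap_fraction must be in [0, 1)")
  if (demean) series <- series - mean(series)
  step <- max(1L, round(nwin * (1 - overlap_fraction)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L))  # Hamming
  u <- sum(w^2)
  acc <- numeric(nwin)
  for (s in starts) {
    seg <- series[s:(s + nwin - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / (length(starts) * u * fs)
  half <- floor(nwin / 2)
  power <- acc[1:(half + 1L)]
  # one-sided: double everything except DC (and Nyquist for even nwin)
  dbl <- 2:(half + if (nwin %% 2L == 0L) 0L else 1L)
  power[dbl] <- 2 * power[dbl]
  structure(list(freqs = (0:half) * fs / nwin, power = power),
            class = "spectrum_psd")
}

#' Fit the aperiodic 1/f^chi component of a power spectrum
#'
#' Robust iterative fit of `log10 P(f) = offset - chi * log10 f` over
#' `fit_range`: (1) ordinary least squares in log-log space; (2) compute
#' residuals; (3) exclude points whose residual exceeds
#' `peak_threshold` robust scale units (MAD) above the line — positive
#' residuals only, i.e. oscillatory peaks; (4) refit; iterate until the
#' excluded set stabilizes (at most `max_iter` passes). A noiseless power law
#' is recovered to machine precision.
#'
#' @param spectrum A `spectrum_psd` (or list with `freqs`, `power`).
#' @param fit_range Frequency range `c(low, high)` in Hz; default 1-40 Hz
#'   (clear of the acquisition high-pass shoulder and mains region).
#' @param peak_threshold Exclusion threshold in robust-scale units
#'   (default 2.5).
#' @param max_iter Maximum refit passes (default 10).
#' @return Object of class `aperiodic_fit`: list with `offset` (log10 power
#'   at 1 Hz), `exponent` (chi), `fit_error` (RMSE of log10 residuals over
#'   retained points), `fit_range`, `n_points`, `excluded` (indices into the
#'   in-range grid).
#' @examples
#' f <- seq(1, 40, by = 0.5)
#' sp <- list(freqs = f, power = 10^1.4 / f^2)
#' coef(fit_aperiodic(sp))
#' @export
fit_aperiodic <- function(spectrum, fit_range = c(1, 40),
                          peak_threshold = 2.5, max_iter = 10L) {
  f <- spectrum$freqs
  p <- spectrum$power
  keep <- f >= fit_range[1L] & f <= fit_range[2L] & f > 0
  if (sum(keep) < 10L)
    stopf("fewer than 10 frequency points inside the fit range")
  f <- f[keep]; p <- p[keep]
  if (any(p <= 0)) stopf("non-positive power inside the fit range")
  lf <- log10(f); lp <- log10(p)

  ols <- function(use) {
    x <- lf[use]; y <- lp[use]
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    c(a, b)
  }
  use <- rep(TRUE, length(lf))
  for (it in seq_len(max_iter)) {
    cf <- ols(use)
    resid <- lp - (cf[1L] + cf[2L] * lf)
    # floor keeps numerically-exact fits (residual spread ~ eps) stable
    scale <- max(stats::mad(resid[use]), 1e-6)
    new_use <- resid <= peak_threshold * scale   # drop only upward outliers
    if (sum(new_use) < 5L)
      stopf("degenerate fit: fewer than 5 points after peak exclusion")
    if (identical(new_use, use)) break
    use <- new_use
  }
  cf <- ols(use)
  resid <- lp[use] - (cf[1L] + cf[2L] * lf[use])
  structure(list(offset = cf[1L], exponent = -cf[2L],
                 fit_error = sqrt(mean(resid^2)),
                 fit_range = fit_range, n_points = sum(use),
                 excluded = which(!use)),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "<aperiodic_fit> offset = %.3f, exponent = %.3f (RMSE %.2g, %d pts, %d excluded, %g-%g Hz)\n",
    x$offset, x$exponent, x$fit_error, x$n_points, length(x$excluded),
    x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' @export
coef.aperiodic_fit <- function(object, ...) {
  c(offset = object$offset, exponent = object$exponent)
}

#' Aperiodic parameters per channel and epoch
#'
#' Applies [welch_psd()] then [fit_aperiodic()] to every channel of every
#' epoch of a broadband (re-referenced, unband-filtered) epoch set.
#'
#' @param epochs An [eeg_epochs] object (broadband).
#' @param fit_range Passed to [fit_aperiodic()].
#' @param window_seconds,overlap_fraction Passed to [welch_psd()].
#' @return Object of class `aperiodic_result`: list with `offset` and
#'   `exponent` (matrices epoch x channel), `fit_error` (same shape), and
#'   `channel_labels`.
#' @export
aperiodic_per_epoch <- function(epochs, fit_range = c(1, 40),
                                window_seconds = 2, overlap_fraction = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ne <- n_epochs(epochs); nc <- n_channels(epochs)
  off <- ex <- err <- matrix(NA_real_, ne, nc,
                             dimnames = list(NULL, epochs$channel_labels))
  for (e in seq_len(ne)) {
    m <- epoch_matrix(epochs, e)
    for (ch in seq_len(nc)) {
      sp <- welch_psd(m[ch, ], epochs$fs, window_seconds, overlap_fraction)
      fit <- fit_aperiodic(sp, fit_range)
      off[e, ch] <- fit$offset
      ex[e, ch] <- fit$exponent
      err[e, ch] <- fit$fit_error
    }
  }
  structure(list(offset = off, exponent = ex, fit_error = err,
                 channel_labels = epochs$channel_labels,
                 fit_range = fit_range),
            class = "aperiodic_result")
}

#' @export
print.aperiodic_result <- function(x, ...) {
  cat(sprintf("<aperiodic_result> %d epoch(s) x %d channel(s)\n",
              nrow(x$offset), ncol(x$offset)))
  cat(sprintf("  offset: median %.3f  exponent: median %.3f\n",
              stats::median(x$offset), stats::median(x$exponent)))
  invisible(x)
}

#' Aggregate aperiodic parameters to global and regional scales
#'
#' Per-epoch mean over all channels (global) or over each region's member
#' channels, separately for offset and exponent. The global value equals the
#' region-size-weighted mean of the regional values.
#'
#' @param fits An `aperiodic_result` from [aperiodic_per_epoch()].
#' @param montage An [montage()].
#' @return List with, for each of `offset` and `exponent`: `global` (numeric
#'   per epoch) and `regional` (matrix epoch x region, `NA` with a warning
#'   for empty regions).
#' @export
aggregate_aperiodic <- function(fits, montage = default_montage()) {
  stopifnot(inherits(fits, "aperiodic_result"))
  agg_one <- function(m) {
    reg <- matrix(NA_real_, nrow(m), length(.region_levels),
                  dimnames = list(NULL, .region_levels))
    for (r in .region_levels) {
      members <- intersect(montage$labels[montage$region == r],
                           colnames(m))
      if (!length(members)) {
        warnf("region '%s' has no channels; regional aperiodic undefined", r)
        next
      }
      reg[, r] <- rowMeans(m[, members, drop = FALSE])
    }
    list(global = rowMeans(m), regional = reg)
  }
  list(offset = agg_one(fits$offset), exponent = agg_one(fits$exponent))
}
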
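# Synthetic EEG generator: 1/f^chi backgrounds, band-limited oscillations
# with von Mises phase coupling, zero-lag volume-conduction mixing, and
# clinical cohorts with known pre->post ground truth.

#' Aperiodic spectrum specification
#'
#' @param offset log10 power (uV^2/Hz) at 1 Hz.
#' @param exponent Spectral exponent chi >= 0.
#' @return List of class `aperiodic_spec`.
#' @export
aperiodic_spec <- function(offset, exponent) {
  if (!is.finite(offset)) stopf("offset must be finite")
  if (!is.finite(exponent) || exponent < 0)
    stopf("exponent must be finite and >= 0")
  structure(list(offset = offset, exponent = exponent),
            class = "aperiodic_spec")
}

#' Phase-coupling specification for a channel pair
#'
#' Describes one band-limited oscillation shared by two channels with a
#' constant mean phase lag `lag_delta` and von Mises phase jitter of
#' concentration `jitter_kappa` (0 = uniform phase difference, large kappa =
#' nearly constant lag).
#'
#' @param channel_pair Character vector of two channel labels.
#' @param band Band name (one of delta, theta, alpha, beta, gamma).
#' @param lag_delta Mean phase lag in radians, in `(-pi, pi]`. Must be
#'   nonzero for the pair to carry any expected PLI.
#' @param jitter_kappa von Mises concentration, >= 0.
#' @param amplitude Carrier amplitude (uV), > 0.
#' @param carrier_hz Carrier frequency; default the band's center.
#' @return List of class `coupling_spec`.
#' @export
coupling_spec <- function(channel_pair, band, lag_delta, jitter_kappa = 10,
                          amplitude = 10, carrier_hz = NULL) {
  if (!band %in% .band_names) stopf("unknown band '%s'", band)
  if (!is.finite(lag_delta) || lag_delta <= -pi || lag_delta > pi)
    stopf("lag_delta must lie in (-pi, pi]")
  if (!is.finite(jitter_kappa) || jitter_kappa < 0)
    stopf("jitter_kappa must be >= 0")
  if (!is.finite(amplitude) || amplitude <= 0)
    stopf("amplitude must be > 0")
  bd <- band_definitions(band)
  if (is.null(carrier_hz)) carrier_hz <- (bd$low + bd$high) / 2
  if (carrier_hz < bd$low || carrier_hz > bd$high)
    stopf("carrier (%g Hz) outside the %s passband", carrier_hz, band)
  structure(list(channel_pair = as.character(channel_pair), band = band,
                 lag_delta = lag_delta, jitter_kappa = jitter_kappa,
                 amplitude = amplitude, carrier_hz = carrier_hz),
            class = "coupling_spec")
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampling; uniform for `kappa = 0`, wrapped-normal
#' approximation (`sd = 1/sqrt(kappa)`) for very large concentration.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration >= 0.
#' @return Angles in `(-pi, pi]`.
#' @export
rvon_mises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 1e3) return(wrap_phase(mu + stats::rnorm(n, 0, 1 / sqrt(kappa))))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    fq <- (1 + r * z) / (r + z)
    cc <- kappa * (r - fq)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(fq[ok])
    out <- c(out, theta)
  }
  wrap_phase(mu + out[seq_len(n)])
}

#' Expected PLI under the von Mises phase-difference model
#'
#' For a phase difference distributed von Mises with mean `lag_delta` and
#' concentration `jitter_kappa`, the PLI expectation is
#' `|P(d in (0, pi)) - P(d in (-pi, 0))|`, evaluated by numeric integration
#' of the wrapped density. This is the independent oracle the simulator's
#' empirical PLI is validated against.
#'
#' @param lag_delta Mean phase lag (radians).
#' @param jitter_kappa Concentration >= 0.
#' @return Scalar in `[0, 1]`.
#' @examples
#' expected_pli(pi / 4, 0)    # uniform difference -> 0
#' expected_pli(0, 5)         # symmetric about zero -> 0
#' expected_pli(pi / 2, 5)
#' @export
expected_pli <- function(lag_delta, jitter_kappa) {
  if (jitter_kappa < 0) stopf("jitter_kappa must be >= 0")
  if (jitter_kappa == 0) return(0)
  # exp-scaled density avoids Bessel overflow at large kappa
  dens <- function(x)
    exp(jitter_kappa * (cos(x - lag_delta) - 1)) /
      (2 * pi * besselI(jitter_kappa, 0, expon.scaled = TRUE))
  p_pos <- stats::integrate(dens, 0, pi, rel.tol = 1e-10)$value
  abs(2 * p_pos - 1)
}

# kappa achieving a target expected PLI at a given lag (inverse oracle)
.kappa_for_pli <- function(target, lag_delta = pi / 4) {
  stopifnot(target >= 0, target < 1)
  if (target == 0) return(0)
  stats::uniroot(function(k) expected_pli(lag_delta, k) - target,
                 lower = 1e-6, upper = 500, tol = 1e-8)$root
}

#' Generate a 1/f^chi background series
#'
#' Inverse-spectral synthesis: the amplitude spectrum is shaped as the square
#' root of the target one-sided power law `10^offset / f^exponent` over the
#' synthesis band, phases are independently uniform, and the result is
#' transformed to the time domain (a stationary Gaussian-like surrogate with
#' exact expected spectrum and zero mean).
#'
#' @param spec An [aperiodic_spec()].
#' @param fs Sampling rate (Hz).
#' @param n_samples Series length (>= 2).
#' @param seed Optional integer seed.
#' @param band Synthesis band in Hz; default `c(0.5, min(70, fs/2))`,
#'   mirroring a 0.5-70 Hz acquisition bandpass.
#' @return Numeric vector of length `n_samples` (zero mean).
#' @export
generate_aperiodic_background <- function(spec, fs, n_samples, seed = NULL,
                                          band = c(0.5, min(70, fs / 2))) {
  if (!inherits(spec, "aperiodic_spec"))
    spec <- do.call(aperiodic_spec, as.list(spec))
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  if (fs <= 0) stopf("fs must be > 0")
  with_seed(seed, {
    n <- as.integer(n_samples)
    half <- floor(n / 2)
    k <- 1:half
    f <- k * fs / n
    amp <- numeric(half)
    inband <- f >= band[1L] & f <= band[2L]
    psd <- 10^spec$offset / f[inband]^spec$exponent
    amp[inband] <- sqrt(psd * fs * n / 2)
    phase <- stats::runif(half, -pi, pi)
    X <- complex(modulus = amp, argument = phase)
    full <- complex(real = numeric(n))
    full[k + 1L] <- X
    idx <- n - k + 1L
    keep <- idx > half + 1L
    full[idx[keep]] <- Conj(X[keep])
    if (n %% 2L == 0L) full[half + 1L] <- 0  # drop Nyquist line
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}

#' Generate a pair of phase-coupled band-limited oscillations
#'
#' Channel a carries `A cos(2 pi f0 t + phi0)`; channel b carries the same
#' oscillation retarded by `lag_delta` plus von Mises jitter, redrawn every
#' `jitter_block_seconds` so the instantaneous phase difference is von Mises
#' distributed yet slowly varying enough for analytic-signal phase tracking.
#'
#' @param coupling A [coupling_spec()].
#' @param fs Sampling rate (Hz).
#' @param n_samples Series length.
#' @param seed Optional integer seed.
#' @param jitter_block_seconds Jitter holding time (default 0.25 s).
#' @return A `2 x n_samples` matrix (rows a, b) with attribute `"phases"`
#'   (the true instantaneous phases, same shape).
#' @export
generate_coupled_oscillation <- function(coupling, fs, n_samples, seed = NULL,
                                         jitter_block_seconds = 0.25) {
  stopifnot(inherits(coupling, "coupling_spec"))
  with_seed(seed, {
    n <- as.integer(n_samples)
    t <- (0:(n - 1L)) / fs
    phi0 <- stats::runif(1L, -pi, pi)
    phase_a <- 2 * pi * coupling$carrier_hz * t + phi0
    block <- max(1L, round(jitter_block_seconds * fs))
    n_blocks <- ceiling(n / block)
    jit <- rvon_mises(n_blocks, 0, coupling$jitter_kappa)
    jit_t <- rep(jit, each = block)[1:n]
    phase_b <- phase_a - coupling$lag_delta - jit_t
    out <- rbind(a = coupling$amplitude * cos(phase_a),
                 b = coupling$amplitude * cos(phase_b))
    attr(out, "phases") <- rbind(a = wrap_phase(phase_a),
                                 b = wrap_phase(phase_b))
    out
  })
}

#' Zero-lag volume-conduction mixing
#'
#' Replaces each channel by the strictly sample-synchronous convex mixture
#' `(1 - leakage) * x_i + leakage * mean_j x_j` with the instantaneous
#' spatial mean. At `leakage = 0` this is the identity; as `leakage -> 1`
#' all channels collapse onto the common mean. Zero-lag mixing changes
#' per-channel spectra but cannot create nonzero-lag phase coupling, so PLI
#' between independent sources stays near zero.
#'
#' @param epochs An [eeg_epochs] object.
#' @param leakage Mixing strength in `[0, 1)`.
#' @return Mixed `eeg_epochs`.
#' @export
mix_volume_conduction <- function(epochs, leakage) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (leakage < 0 || leakage >= 1) stopf("leakage must be in [0, 1)")
  if (leakage == 0) return(epochs)
  m <- apply(epochs$data, c(1L, 3L), mean)          # epoch x sample means
  mix <- aperm(array(m, c(dim(m), dim(epochs$data)[2L])), c(1L, 3L, 2L))
  replace_data(epochs, (1 - leakage) * epochs$data + leakage * mix)
}

#' Simulation configuration for one epoch set
#'
#' Defaults are the reference acquisition: 61 channels, 1,024 Hz, 20 epochs
#' of 8 s (8,192 samples).
#'
#' @param n_channels Number of channels (default 61); ignored if
#'   `channel_labels` is given.
#' @param fs Sampling rate (default 1024 Hz).
#' @param epoch_seconds Epoch length (default 8 s); `fs * epoch_seconds`
#'   must be integral.
#' @param n_epochs Number of epochs (default 20).
#' @param aperiodic An [aperiodic_spec()] applied to every channel, or a
#'   list of one spec per channel.
#' @param couplings List of [coupling_spec()].
#' @param leakage Volume-conduction mixing in `[0, 1)` (default 0.2).
#' @param channel_labels Channel labels (default: first `n_channels` of the
#'   61-channel montage).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_channels = 61L, fs = 1024, epoch_seconds = 8,
                       n_epochs = 20L,
                       aperiodic = aperiodic_spec(1.4, 2.0),
                       couplings = list(), leakage = 0.2,
                       channel_labels = NULL, seed = 1L) {
  if (is.null(channel_labels)) {
    if (n_channels > length(.montage_labels_61))
      stopf("n_channels > 61 requires explicit channel_labels")
    channel_labels <- .montage_labels_61[seq_len(n_channels)]
  }
  channel_labels <- normalize_channel_labels(channel_labels)
  if (anyDuplicated(channel_labels)) stopf("duplicate channel labels")
  n_channels <- length(channel_labels)
  ns <- fs * epoch_seconds
  if (abs(ns - round(ns)) > 1e-9)
    stopf("epoch_seconds * fs must be integral")
  if (n_epochs < 1L) stopf("n_epochs must be >= 1")
  if (inherits(aperiodic, "aperiodic_spec"))
    aperiodic <- rep(list(aperiodic), n_channels)
  if (length(aperiodic) != n_channels)
    stopf("need one aperiodic spec per channel")
  for (cp in couplings) {
    if (!all(cp$channel_pair %in% channel_labels))
      stopf("coupling references unknown channel(s): %s",
            paste(setdiff(cp$channel_pair, channel_labels), collapse = ", "))
  }
  structure(list(n_channels = n_channels, fs = fs,
                 epoch_seconds = epoch_seconds, n_epochs = as.integer(n_epochs),
                 aperiodic = aperiodic, couplings = couplings,
                 leakage = leakage, channel_labels = channel_labels,
                 seed = seed),
            class = "sim_config")
}

#' Generate a synthetic epoch set
#'
#' Each channel is an independent 1/f^chi background; each coupling adds its
#' oscillation pair to the two named channels; finally zero-lag
#' volume-conduction mixing is applied. Bit-reproducible under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param subject_id,session Metadata tags for the returned [eeg_epochs].
#' @return An [eeg_epochs] of shape
#'   `(n_epochs, n_channels, fs * epoch_seconds)`.
#' @export
generate_epoch_set <- function(config, subject_id = NA_character_,
                               session = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  ns <- as.integer(round(config$fs * config$epoch_seconds))
  with_seed(config$seed, {
    d <- array(0, c(config$n_epochs, config$n_channels, ns))
    ci <- match(vapply(config$couplings, function(cp) cp$channel_pair[1L], ""),
                config$channel_labels)
    cj <- match(vapply(config$couplings, function(cp) cp$channel_pair[2L], ""),
                config$channel_labels)
    for (e in seq_len(config$n_epochs)) {
      for (ch in seq_len(config$n_channels))
        d[e, ch, ] <- generate_aperiodic_background(
          config$aperiodic[[ch]], config$fs, ns)
      for (k in seq_along(config$couplings)) {
        osc <- generate_coupled_oscillation(config$couplings[[k]],
                                            config$fs, ns)
        d[e, ci[k], ] <- d[e, ci[k], ] + osc["a", ]
        d[e, cj[k], ] <- d[e, cj[k], ] + osc["b", ]
      }
    }
    out <- eeg_epochs(d, config$fs, config$channel_labels,
                      subject_id = subject_id, session = session)
    mix_volume_conduction(out, config$leakage)
  })
}
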
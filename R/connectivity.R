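# Phase lag index (PLI) connectivity.
#
# PLI between two signals is the absolute mean of the sign of their wrapped
# instantaneous phase difference: 0 for no consistently lagged coupling, 1
# for a perfectly consistent nonzero lag. Because exactly zero-lag phase
# differences contribute sign 0, the index discounts instantaneous
# (volume-conducted) coupling.

# analytic signal of each row of a channels x samples matrix via FFT
.analytic_matrix <- function(m) {
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  sp <- t(stats::mvfft(t(m)))
  t(stats::mvfft(t(sp * rep(h, each = nrow(m))), inverse = TRUE)) / n
}

#' Instantaneous phase of band-limited epochs
#'
#' Computes the analytic signal (the series plus its quadrature component)
#' per channel and epoch, and returns its argument. Input should be
#' narrowband (a [apply_band_filter()] output) for the phase to be
#' interpretable.
#'
#' @param band_epochs An [eeg_epochs] object (one band).
#' @return A list of class `phase_epochs`: `phases` is an array
#'   `(epoch, channel, sample)` of radians in `(-pi, pi]`; `fs`,
#'   `channel_labels` carried over.
#' @export
instantaneous_phase <- function(band_epochs) {
  stopifnot(inherits(band_epochs, "eeg_epochs"))
  d <- band_epochs$data
  ph <- array(0, dim(d))
  for (e in seq_len(dim(d)[1L])) {
    m <- epoch_matrix(band_epochs, e)
    v <- apply(m, 1L, stats::var)
    if (any(v == 0))
      stopf("constant channel(s) have undefined phase: %s",
            paste(band_epochs$channel_labels[v == 0], collapse = ", "))
    ph[e, , ] <- Arg(.analytic_matrix(m))
  }
  structure(list(phases = ph, fs = band_epochs$fs,
                 channel_labels = band_epochs$channel_labels),
            class = "phase_epochs")
}

#' Phase lag index of a pair of phase series
#'
#' `PLI = | mean_t sign( wrap(phase_a - phase_b) ) |` with the difference
#' wrapped to `(-pi, pi]` and `sign(0) = 0`.
#'
#' @param phase_a,phase_b Numeric vectors of equal length (radians).
#' @return Scalar in `[0, 1]`.
#' @examples
#' pli_pair(rep(pi / 4, 10), rep(0, 10))  # constant lag -> 1
#' pli_pair(1:10, 1:10)                   # identical -> 0
#' @export
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stopf("phase series lengths differ (%d vs %d)",
          length(phase_a), length(phase_b))
  if (length(phase_a) < 2L) stopf("need at least 2 samples")
  abs(mean(sign(sin(phase_a - phase_b))))
}

# sign(wrap(d)) == sign(sin(d)) for all d not congruent to 0 or pi; at
# multiples of pi both are 0 (sin) or the wrap boundary, where the spec's
# sign(0) = 0 convention is what sin delivers at d = 0. At d = pi the wrapped
# difference is +pi (sign +1) but sin gives 0; exact +/-pi differences are
# measure-zero and treated as zero-lag-ambiguous.

#' PLI matrix of one phase epoch
#'
#' @param phase_epochs A `phase_epochs` object from [instantaneous_phase()].
#' @param epoch Epoch index.
#' @return Symmetric `n_channels x n_channels` matrix, zero diagonal,
#'   entries in `[0, 1]`.
#' @export
pli_matrix <- function(phase_epochs, epoch = 1L) {
  stopifnot(inherits(phase_epochs, "phase_epochs"))
  ph <- phase_epochs$phases[epoch, , , drop = FALSE]
  dim(ph) <- dim(phase_epochs$phases)[2:3]
  nc <- nrow(ph)
  if (nc < 2L) stopf("need at least 2 channels")
  out <- .pli_matrix_phases(ph)
  dimnames(out) <- list(phase_epochs$channel_labels,
                        phase_epochs$channel_labels)
  out
}

# core PLI matrix from a channels x samples phase matrix;
# sign(sin(a - b)) = sign(sin a cos b - cos a sin b), so sin/cos are
# precomputed once per channel; the pair loop runs compiled
.pli_matrix_phases <- function(ph) {
  tp <- t(ph)
  .pli_matrix_sc(sin(tp), cos(tp))
}

#' Per-epoch, per-band PLI with global / regional / channel aggregates
#'
#' Runs [instantaneous_phase()] and [pli_matrix()] over every epoch of every
#' band and aggregates each matrix at the three spatial scales the analysis
#' uses: global (mean over all unordered channel pairs), regional (mean over
#' within-region pairs only) and channel (mean over all pairs involving the
#' channel). Epoch-level values are retained — they are the statistical unit
#' downstream.
#'
#' @param band_stack Named list of band-filtered [eeg_epochs]
#'   (see [extract_band_stack()]).
#' @param montage An [montage()] covering the channels.
#' @return Object of class `connectivity_result`: list with `matrices`
#'   (per band: array `(epoch, channel, channel)`), `global` (per band:
#'   numeric per epoch), `regional` (per band: matrix epoch x region),
#'   `channel` (per band: matrix epoch x channel), plus `montage`.
#' @export
pli_connectivity <- function(band_stack, montage = default_montage()) {
  stopifnot(is.list(band_stack), !is.null(names(band_stack)))
  res <- list(matrices = list(), global = list(), regional = list(),
              channel = list(), montage = montage)
  for (b in names(band_stack)) {
    pe <- instantaneous_phase(band_stack[[b]])
    ne <- dim(pe$phases)[1L]
    nc <- dim(pe$phases)[2L]
    mats <- array(0, c(ne, nc, nc))
    for (e in seq_len(ne)) mats[e, , ] <- pli_matrix(pe, e)
    dimnames(mats) <- list(NULL, pe$channel_labels, pe$channel_labels)
    res$matrices[[b]] <- mats
    res$global[[b]] <- aggregate_global(mats)
    res$regional[[b]] <- aggregate_region(mats, montage)
    res$channel[[b]] <- aggregate_channel(mats)
  }
  class(res) <- "connectivity_result"
  res
}

#' @export
print.connectivity_result <- function(x, ...) {
  bands <- names(x$matrices)
  ne <- dim(x$matrices[[1L]])[1L]
  nc <- dim(x$matrices[[1L]])[2L]
  cat(sprintf("<connectivity_result> %d band(s), %d epoch(s), %d channel(s)\n",
              length(bands), ne, nc))
  g <- vapply(x$global, mean, 0)
  cat("  mean global PLI:",
      paste(sprintf("%s=%.3f", bands, g), collapse = "  "), "\n")
  invisible(x)
}

# accept either a single matrix or an (epoch, ch, ch) array
.as_mat_array <- function(m) {
  if (is.matrix(m)) m <- array(m, c(1L, dim(m)), dimnames = c(list(NULL), dimnames(m)))
  stopifnot(length(dim(m)) == 3L, dim(m)[2L] == dim(m)[3L])
  m
}

#' Global PLI: per-epoch mean over all unordered channel pairs
#'
#' @param matrices A symmetric PLI matrix or an `(epoch, channel, channel)`
#'   array of them.
#' @return Numeric vector, one value per epoch.
#' @export
aggregate_global <- function(matrices) {
  m <- .as_mat_array(matrices)
  nc <- dim(m)[2L]
  if (nc < 2L) stopf("need at least 2 channels")
  apply(m, 1L, function(mm) mean(mm[upper.tri(mm)]))
}

#' Regional PLI: per-epoch mean over within-region channel pairs
#'
#' Regions with fewer than two member channels have no within-region pair and
#' are reported as `NA` (flagged by a warning).
#'
#' @inheritParams aggregate_global
#' @param montage An [montage()]; its labels must all be present in the
#'   matrices' dimnames.
#' @return Matrix epoch x region.
#' @export
aggregate_region <- function(matrices, montage = default_montage()) {
  m <- .as_mat_array(matrices)
  labs <- dimnames(m)[[2L]]
  if (is.null(labs)) stopf("matrices must carry channel labels as dimnames")
  out <- matrix(NA_real_, dim(m)[1L], length(.region_levels),
                dimnames = list(NULL, .region_levels))
  for (r in .region_levels) {
    members <- intersect(montage$labels[montage$region == r], labs)
    if (length(members) < 2L) {
      warnf("region '%s' has %d channel(s); regional PLI undefined",
            r, length(members))
      next
    }
    idx <- match(members, labs)
    out[, r] <- apply(m, 1L, function(mm) {
      sub <- mm[idx, idx]
      mean(sub[upper.tri(sub)])
    })
  }
  out
}

#' Channel PLI: per-epoch mean over all pairs involving each channel
#'
#' For channel i this is the mean of row i of the PLI matrix excluding the
#' diagonal. Averaging these channel values over all channels recovers the
#' global value exactly (every pair appears twice in both numerator and
#' denominator).
#'
#' @inheritParams aggregate_global
#' @return Matrix epoch x channel.
#' @export
aggregate_channel <- function(matrices) {
  m <- .as_mat_array(matrices)
  nc <- dim(m)[2L]
  if (nc < 2L) stopf("need at least 2 channels")
  out <- t(apply(m, 1L, function(mm) rowSums(mm) / (nc - 1L)))
  colnames(out) <- dimnames(m)[[2L]]
  out
}
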
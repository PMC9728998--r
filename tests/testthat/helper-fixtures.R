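# Shared fixtures: all synthetic, built in code.

# epochs holding pure sinusoids (one frequency per channel)
sine_epochs <- function(freqs, fs = 256, seconds = 8, labels = NULL,
                        n_epochs = 1L, amplitude = 1) {
  n <- fs * seconds
  t <- (0:(n - 1)) / fs
  if (is.null(labels)) labels <- paste0("C", seq_along(freqs))
  d <- array(0, c(n_epochs, length(freqs), n))
  for (e in seq_len(n_epochs))
    for (ch in seq_along(freqs))
      d[e, ch, ] <- amplitude * sin(2 * pi * freqs[ch] * t)
  eeg_epochs(d, fs, labels)
}

# white-noise epochs
noise_epochs <- function(n_channels = 2L, fs = 256, seconds = 8,
                         n_epochs = 1L, labels = NULL, sd = 1) {
  n <- fs * seconds
  if (is.null(labels)) labels <- vnseeg:::.cohort_labels_19[seq_len(n_channels)]
  eeg_epochs(array(stats::rnorm(n_epochs * n_channels * n, sd = sd),
                   c(n_epochs, n_channels, n)), fs, labels)
}

# a fast, tiny cohort world for smoke tests (not the acceptance world)
tiny_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(n_responders = 2L, n_nonresponders = 2L, n_epochs = 3L,
              seed = seed, ...)
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- i:m
    adj[o[i]] <- min(1, min(m * p[o[k]] / k))
  }
  adj
}

# brute-force two-sided Mann-Whitney p by enumerating rank assignments
mwu_enumerate <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(pooled), n1), 2L,
              function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
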
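test_that("aperiodic background has the requested power-law spectrum", {
  # exponent 0 degenerates to a flat spectrum
  x <- generate_aperiodic_background(aperiodic_spec(0.5, 0), 256, 2048,
                                     seed = 1)
  fit <- fit_aperiodic(welch_psd(x, 256))
  expect_lt(abs(fit$exponent), 0.1)

  # +1 offset with the same seed multiplies power by exactly 10
  a <- generate_aperiodic_background(aperiodic_spec(0.4, 1.5), 256, 2048,
                                     seed = 7)
  b <- generate_aperiodic_background(aperiodic_spec(1.4, 1.5), 256, 2048,
                                     seed = 7)
  expect_equal(b, sqrt(10) * a, tolerance = 1e-12)

  expect_error(generate_aperiodic_background(list(offset = 1, exponent = -1),
                                             256, 2048), "exponent")
  expect_error(generate_aperiodic_background(list(offset = Inf, exponent = 1),
                                             256, 2048), "offset")
})

test_that("background generator recovers (1.4, 2.0) within 0.1 at 20 epochs", {
  cf <- rowMeans(vapply(1:20, function(e) {
    x <- generate_aperiodic_background(aperiodic_spec(1.4, 2.0), 1024, 8192,
                                       seed = 100 + e)
    coef(fit_aperiodic(welch_psd(x, 1024)))
  }, c(offset = 0, exponent = 0)))
  expect_lt(abs(cf[["offset"]] - 1.4), 0.1)
  expect_lt(abs(cf[["exponent"]] - 2.0), 0.1)
})

test_that("mean spectrum over 100 epochs recovers parameters within 0.05", {
  sp <- welch_psd(generate_aperiodic_background(aperiodic_spec(1.0, 1.5),
                                                256, 2048, seed = 1), 256)
  acc <- sp$power
  for (e in 2:100) {
    x <- generate_aperiodic_background(aperiodic_spec(1.0, 1.5), 256, 2048,
                                       seed = e)
    acc <- acc + welch_psd(x, 256)$power
  }
  keep <- sp$freqs >= 1 & sp$freqs <= 40
  cf <- stats::coef(stats::lm(log10(acc[keep] / 100) ~ log10(sp$freqs[keep])))
  expect_lt(abs(cf[[1]] - 1.0), 0.05)
  expect_lt(abs(-cf[[2]] - 1.5), 0.05)
})

test_that("expected_pli matches closed forms and Monte-Carlo to 3 decimals", {
  expect_identical(expected_pli(1.2, 0), 0)        # uniform difference
  expect_equal(expected_pli(0, 5), 0, tolerance = 1e-9)  # symmetric density
  expect_equal(expected_pli(-pi / 3, 2), expected_pli(pi / 3, 2))
  # independent oracle: direct von Mises sampling
  set.seed(42)
  mc <- abs(mean(sign(sin(rvon_mises(1e6, pi / 2, 5)))))
  expect_equal(expected_pli(pi / 2, 5), mc, tolerance = 1.5e-3)
  # huge concentration: all mass on one side of zero
  expect_equal(expected_pli(pi / 4, 1e5), 1, tolerance = 1e-6)
  expect_error(expected_pli(0.2, -1), "kappa")
})

test_that("coupled oscillation pair realizes the von Mises phase model", {
  # constant nonzero lag: PLI exactly 1
  cp <- coupling_spec(c("C3", "C4"), "alpha", pi / 4, jitter_kappa = 1e4)
  osc <- generate_coupled_oscillation(cp, 256, 2048, seed = 5)
  ph <- attr(osc, "phases")
  expect_identical(pli_pair(ph["a", ], ph["b", ]), 1)

  # zero lag: sign distribution symmetric about 0, PLI near 0
  # (per-sample jitter so each epoch holds many independent sign draws)
  cp0 <- coupling_spec(c("C3", "C4"), "alpha", lag_delta = 0, jitter_kappa = 2)
  vals0 <- vapply(1:50, function(e) {
    p <- attr(generate_coupled_oscillation(cp0, 256, 2048, seed = e,
                                           jitter_block_seconds = 1 / 256),
              "phases")
    pli_pair(p["a", ], p["b", ])
  }, 0)
  expect_lt(mean(vals0), 0.05)

  # (pi/4, kappa = 2): empirical mean within 3 SE of the numeric oracle
  cp2 <- coupling_spec(c("C3", "C4"), "alpha", pi / 4, jitter_kappa = 2)
  vals <- vapply(1:200, function(e) {
    p <- attr(generate_coupled_oscillation(cp2, 1024, 8192, seed = e),
              "phases")
    pli_pair(p["a", ], p["b", ])
  }, 0)
  th <- expected_pli(pi / 4, 2)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - th), 3 * se)

  # carrier sits inside the band's passband
  sp <- welch_psd(osc["a", ], 256)
  f_peak <- sp$freqs[which.max(sp$power)]
  expect_gte(f_peak, 8); expect_lte(f_peak, 12)

  expect_error(coupling_spec(c("a", "b"), "alpha", lag_delta = -pi), "lag")
  expect_error(coupling_spec(c("a", "b"), "sigma", pi / 4), "unknown band")
})

test_that("zero-lag mixing is convex, degenerate at the ends, PLI-neutral", {
  set.seed(21)
  ep <- noise_epochs(n_channels = 3L, fs = 128, seconds = 4)
  expect_identical(mix_volume_conduction(ep, 0), ep)
  expect_error(mix_volume_conduction(ep, 1), "leakage")

  # leakage -> 1: all channels collapse onto the common mean
  mx <- mix_volume_conduction(ep, 0.999)
  spread <- apply(mx$data, c(1, 3), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-2 * max(abs(ep$data)))

  # mixed independent noise keeps pairwise PLI near zero
  vals <- vapply(1:30, function(e) {
    set.seed(300 + e)
    m <- mix_volume_conduction(noise_epochs(2L, fs = 1024, seconds = 8), 0.4)
    p <- instantaneous_phase(m)
    pli_pair(p$phases[1, 1, ], p$phases[1, 2, ])
  }, 0)
  expect_lt(mean(vals), 0.05)
})

test_that("generate_epoch_set is shape-correct and bit-reproducible", {
  cfg <- sim_config(n_channels = 3L, fs = 128, epoch_seconds = 2,
                    n_epochs = 2L, seed = 9,
                    couplings = list(coupling_spec(c("Fp1", "Fp2"), "alpha",
                                                   pi / 4, 5)))
  a <- generate_epoch_set(cfg)
  b <- generate_epoch_set(cfg)
  expect_identical(a$data, b$data)
  expect_identical(dim(a$data), c(2L, 3L, 256L))

  tiny <- generate_epoch_set(sim_config(n_channels = 2L, fs = 128,
                                        epoch_seconds = 1, n_epochs = 1L,
                                        seed = 1))
  expect_identical(dim(tiny$data), c(1L, 2L, 128L))

  expect_error(sim_config(channel_labels = c("C3", "C3")), "duplicate")
  expect_error(sim_config(n_channels = 2L, fs = 128,
                          couplings = list(coupling_spec(c("O1", "O2"),
                                                         "alpha", pi / 4))),
               "unknown channel")
  expect_error(sim_config(fs = 100, epoch_seconds = 1.505), "integral")
})

test_that("generate_cohort honours the responder threshold and determinism", {
  spec <- tiny_cohort_spec(seed = 31)
  co <- generate_cohort(spec)
  tab <- cohort_table(co)
  cls <- classify_responder(tab$labar)
  expect_identical(cls$group, tab$group)
  expect_identical(sum(tab$group == "R"), 2L)
  expect_true(all(tab$labar[tab$group == "R"] >= 50))
  expect_true(all(tab$labar[tab$group == "NR"] < 50))

  # full remission: all responder post rates 0, Labar exactly 100
  co2 <- generate_cohort(tiny_cohort_spec(
    seed = 32, responder_reduction_range = c(1, 1)))
  t2 <- cohort_table(co2)
  expect_equal(t2$post_rate[t2$group == "R"], c(0, 0))
  expect_equal(t2$labar[t2$group == "R"], c(100, 100))

  # fixed seed: identical cohort, including the EEG
  co3 <- generate_cohort(spec)
  expect_identical(cohort_table(co3), tab)
  expect_identical(co3$subjects[[1]]$pre$data, co$subjects[[1]]$pre$data)

  expect_error(cohort_spec(n_responders = 0L), "at least one")
  expect_error(cohort_spec(responder_reduction_range = c(0.3, 1)), "0.5")
  expect_error(cohort_spec(nonresponder_reduction_range = c(0, 0.7)),
               "threshold")
})
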
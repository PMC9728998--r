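test_that("instantaneous phase satisfies the analytic-signal identities", {
  fs <- 256; t <- (0:2047) / fs
  ep <- eeg_epochs(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t),
                         5 * cos(2 * pi * 10 * t)),
                   fs, c("C3", "C4", "Cz"))
  ph <- instantaneous_phase(ep)$phases

  # phase advances by 2*pi*f/fs per sample (checked away from the edges)
  dphi <- wrap_phase(diff(ph[1, 1, 100:1900]))
  expect_equal(mean(dphi), 2 * pi * 10 / fs, tolerance = 1e-3)

  # cos leads sin by pi/2 at the same frequency
  dd <- wrap_phase(ph[1, 1, 100:1900] - ph[1, 2, 100:1900])
  expect_equal(stats::median(dd), pi / 2, tolerance = 1e-3)

  # phase is amplitude-invariant (compare on the circle: +pi == -pi)
  expect_lt(max(abs(wrap_phase(ph[1, 1, ] - ph[1, 3, ]))), 1e-9)

  # constant channel: undefined phase
  flat <- eeg_epochs(rbind(cos(2 * pi * 10 * t), rep(1, length(t))),
                     fs, c("C3", "C4"))
  expect_error(instantaneous_phase(flat), "constant channel.*C4")
})

test_that("pli_pair implements |mean sign of wrapped difference|", {
  expect_identical(pli_pair(rep(pi / 4, 8), rep(0, 8)), 1)     # constant lag
  expect_identical(pli_pair(rep(0.3, 8), rep(0.3, 8)), 0)      # identical
  expect_identical(pli_pair(c(pi / 4, -pi / 4, pi / 4, -pi / 4),
                            rep(0, 4)), 0)                     # balanced
  expect_error(pli_pair(1:3, 1:4), "lengths differ")

  # invariance to common constant phase and to the argument order
  set.seed(51)
  a <- runif(500, -pi, pi); b <- runif(500, -pi, pi)
  expect_equal(pli_pair(a, b), pli_pair(b, a))
  expect_equal(pli_pair(a + 0.7, b + 0.7), pli_pair(a, b), tolerance = 1e-12)
})

test_that("pli_matrix is symmetric, zero-diagonal and matches pli_pair", {
  set.seed(52)
  fs <- 128
  ep <- noise_epochs(n_channels = 6L, fs = fs, seconds = 4)
  pe <- instantaneous_phase(apply_band_filter(ep, "alpha"))
  m <- pli_matrix(pe)
  expect_identical(dim(m), c(6L, 6L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0 & m <= 1))
  # compiled kernel agrees exactly with the R definition
  for (i in 1:5) for (j in (i + 1):6)
    expect_identical(m[i, j], pli_pair(pe$phases[1, i, ], pe$phases[1, j, ]))
})

test_that("independent broadband noise yields a near-zero PLI matrix", {
  set.seed(53)
  ep <- noise_epochs(n_channels = 8L, fs = 1024, seconds = 8)
  pe <- instantaneous_phase(ep)
  m <- pli_matrix(pe)
  expect_lt(mean(m[upper.tri(m)]), 0.05)
})

test_that("aggregations reduce matrices exactly as defined", {
  labs <- c("Fp1", "Fp2", "Oz")
  toy <- matrix(c(0, 0.2, 0.4,
                  0.2, 0, 0.6,
                  0.4, 0.6, 0), 3, byrow = TRUE,
                dimnames = list(labs, labs))
  expect_equal(aggregate_global(toy), mean(c(0.2, 0.4, 0.6)))
  ch <- aggregate_channel(toy)
  expect_equal(unname(ch[1, ]), c(0.3, 0.4, 0.5))
  # channel mean equals the global value (exact algebraic identity)
  expect_equal(mean(ch), aggregate_global(toy))

  # constant matrix: every aggregate is the constant
  cm <- matrix(0.3, 4, 4) - diag(0.3, 4)
  dimnames(cm) <- list(c("Fp1", "Fp2", "O1", "O2"), c("Fp1", "Fp2", "O1", "O2"))
  expect_equal(aggregate_global(cm), 0.3)
  expect_equal(unname(aggregate_channel(cm)[1, ]), rep(0.3, 4))
  reg <- suppressWarnings(aggregate_region(cm, montage(rownames(cm))))
  expect_equal(unname(reg[1, c("frontal", "occipital")]), c(0.3, 0.3))

  # 2-channel case: global equals the single pair value
  two <- matrix(c(0, 0.7, 0.7, 0), 2,
                dimnames = list(c("C3", "C4"), c("C3", "C4")))
  expect_equal(aggregate_global(two), 0.7)

  # regional aggregation matches the within-region pair enumeration;
  # regions with < 2 channels are flagged undefined
  mt <- montage(labs)
  w <- capture_warnings(r <- aggregate_region(toy, mt))
  expect_true(any(grepl("occipital", w)))
  expect_equal(unname(r[1, "frontal"]), 0.2)
  expect_true(is.na(r[1, "occipital"]))
})

test_that("empirical PLI converges to the von Mises oracle (3 SE, 200 epochs)", {
  cp <- coupling_spec(c("C3", "C4"), "theta", pi / 3, jitter_kappa = 1)
  vals <- vapply(1:200, function(e) {
    p <- attr(generate_coupled_oscillation(cp, 256, 2048, seed = 700 + e),
              "phases")
    pli_pair(p["a", ], p["b", ])
  }, 0)
  th <- expected_pli(pi / 3, 1)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - th), 3 * se)
})

test_that("PLI is invariant to amplitude scaling of the signals", {
  set.seed(54)
  ep <- noise_epochs(n_channels = 2L, fs = 256, seconds = 4)
  sc <- ep
  sc$data[1, 1, ] <- 3 * ep$data[1, 1, ]
  sc$data[1, 2, ] <- 0.2 * ep$data[1, 2, ]
  p1 <- instantaneous_phase(apply_band_filter(ep, "beta"))
  p2 <- instantaneous_phase(apply_band_filter(sc, "beta"))
  expect_equal(pli_pair(p1$phases[1, 1, ], p1$phases[1, 2, ]),
               pli_pair(p2$phases[1, 1, ], p2$phases[1, 2, ]),
               tolerance = 1e-10)
})

test_that("pli_connectivity assembles matrices and all three scales", {
  set.seed(55)
  labs <- c("Fp1", "Fp2", "C3", "C4")
  ep <- noise_epochs(n_channels = 4L, fs = 128, seconds = 2, n_epochs = 3L,
                     labels = labs)
  stack <- extract_band_stack(ep, expected_channels = 4L)
  suppressWarnings(res <- pli_connectivity(stack, montage(labs)))
  expect_s3_class(res, "connectivity_result")
  expect_identical(names(res$matrices),
                   c("delta", "theta", "alpha", "beta", "gamma"))
  expect_identical(dim(res$matrices$alpha), c(3L, 4L, 4L))
  expect_length(res$global$alpha, 3L)
  expect_identical(colnames(res$channel$alpha), labs)
  # identity between scales holds epoch-wise
  expect_equal(rowMeans(res$channel$gamma), res$global$gamma)
})
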
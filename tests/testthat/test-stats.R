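test_that("Mann-Whitney U reproduces exact and approximate references", {
  # complete separation: U = 0, exact two-sided p = 2 * 1/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  # identical multisets: no shift, p near 1
  set.seed(71)
  x <- rnorm(30)
  expect_gt(mann_whitney_u(x, x)$p, 0.9)

  # invariance under a common monotone transform
  y <- rnorm(30) + 0.5
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(exp(x), exp(y))$p)

  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact MWU branch equals full enumeration of rank assignments", {
  set.seed(72)
  for (k in 1:8) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1000, n1) / 7
    y <- sample(1000, n2) / 7
    r <- mann_whitney_u(x, y)
    expect_true(r$exact)
    expect_equal(r$p, mwu_enumerate(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  # hand-applied step-up rule
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04, 0.60))$p_adjusted,
               c(0.04, 0.04, 0.16 / 3, 0.60))
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)          # single p unchanged
  expect_equal(fdr_bh(rep(0.2, 5))$p_adjusted, rep(0.2, 5))  # all equal

  set.seed(73)
  for (k in 1:50) {
    p <- runif(sample(1:12, 1))
    r <- fdr_bh(p)
    expect_equal(r$p_adjusted, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(r$p_adjusted >= p))                # p_fdr >= p_raw
    # significance monotone in alpha
    expect_true(all(fdr_bh(p, 0.01)$significant <= fdr_bh(p, 0.10)$significant))
  }
  expect_error(fdr_bh(c(0.2, 0)), "0, 1")
  expect_error(fdr_bh(c(0.2, 1.4)), "0, 1")
})

test_that("FDR families follow the spatial-subdivision rule", {
  grid <- expand.grid(feature = c("delta", "theta", "alpha", "beta", "gamma"),
                      scale = c("global", "regional"),
                      unit = NA_character_,
                      group = c("R", "NR"), stringsAsFactors = FALSE)
  grid$measure <- "pli"
  grid$unit[grid$scale == "regional"] <- "frontal"
  fam <- build_fdr_families(grid)
  # one family per group x subdivision, each spanning the 5 bands
  expect_identical(as.integer(table(fam)), rep(5L, 4))

  ap <- data.frame(measure = "aperiodic", group = "R", scale = "global",
                   unit = NA_character_, feature = c("offset", "exponent"))
  expect_identical(length(unique(build_fdr_families(ap))), 1L)

  ch <- data.frame(measure = "pli", group = "R", scale = "channel",
                   unit = c("Fp1", "Oz"), feature = "alpha")
  expect_identical(length(unique(build_fdr_families(ch))), 1L)     # pooled
  expect_identical(length(unique(build_fdr_families(
    ch, channel_family = "per_region"))), 2L)

  expect_error(build_fdr_families(data.frame(measure = "pli")), "columns")
})

test_that("Cohen's d uses the pooled-SD formula", {
  x <- c(0, 2); y <- c(-1, 1)   # means 1, 0; both SD sqrt(2)
  expect_equal(cohens_d(x, y), 1 / sqrt(2))
  expect_equal(cohens_d(x, x), 0)
  # equal-n case with s1 = 0.04, s2 = 0.03, means 0.18 vs 0.17
  mk <- function(m, s, n) m + s * scale(seq_len(n))[, 1]
  a <- mk(0.18, 0.04, 9); b <- mk(0.17, 0.03, 9)
  expect_equal(cohens_d(a, b), 0.01 / sqrt((0.04^2 + 0.03^2) / 2),
               tolerance = 1e-9)
  expect_warning(d <- cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_true(is.nan(d))
})

test_that("relative variation compares session medians", {
  expect_equal(relative_variation(c(2, 2, 2), c(1, 1)), -0.5)
  expect_equal(relative_variation(c(5, 1, 3), c(3, 1, 5)), 0)
  expect_equal(relative_variation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_warning(rv <- relative_variation(c(-1, 1), c(1, 2)), "zero pre")
  expect_true(is.nan(rv))
})

test_that("Labar index and responder rule reproduce the printed cohort", {
  tab <- vns_example_cohort()
  # patients 1-9: computed index matches the printed column to 2 decimals
  lab <- labar_index(tab$pre_rate, tab$post_rate)
  expect_equal(round(lab[1:9], 2), tab$labar_printed[1:9])
  # patient 10's printed value is inconsistent with its printed rates
  # (33.00 -> 8.40 gives 74.55, printed 72.00); both sides of the 50%
  # threshold agree, so the responder split is unaffected
  expect_gte(lab[10], 50)
  cls <- classify_responder(lab)
  expect_identical(sum(cls$group == "R"), 5L)
  expect_identical(sum(cls$group == "NR"), 5L)

  expect_equal(labar_index(0, 0), 0)
  expect_warning(li <- labar_index(0, 2), "undefined")
  expect_true(is.nan(li))

  expect_identical(classify_responder(85.67)$bucket, "I")
  expect_identical(classify_responder(62)$bucket, "II")
  expect_identical(classify_responder(50)$group, "R")   # boundary: >= 50
  expect_identical(classify_responder(4.66)$group, "NR")
})

test_that("Spearman correlation matches rank arithmetic", {
  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3)$rho, -1)
  # d^2 = {1,1,1,1}: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3))$rho, 0.6)
  expect_warning(s <- spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.nan(s$rho))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

# build an epoch-level feature table directly (no EEG simulation)
make_feature_frame <- function(shift_nr_offset = 0, seed = 1,
                               n_subj = 5L, n_epochs = 20L) {
  set.seed(seed)
  rows <- list()
  for (g in c("R", "NR")) for (s in seq_len(n_subj)) {
    base <- rnorm(1, 1.4, 0.1)
    for (sess in c("pre", "post")) {
      val <- base + rnorm(n_epochs, 0, 0.05) +
        (sess == "post" && g == "NR") * shift_nr_offset
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0(g, s), group = g, session = sess,
        measure = "aperiodic", feature = "offset", scale = "global",
        unit = NA_character_, epoch = seq_len(n_epochs), value = val,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("compare_groups detects an injected one-group shift", {
  ft <- make_feature_frame(shift_nr_offset = 0.3, seed = 74)
  cmp <- compare_groups(ft)
  nr <- cmp[cmp$group == "NR", ]
  r <- cmp[cmp$group == "R", ]
  expect_true(nr$significant)
  expect_identical(nr$trend, "up")
  expect_false(r$significant)
  expect_identical(r$trend, "none")
  expect_true(all(cmp$p_fdr >= cmp$p_raw))

  # subject-level unit is available and far less powerful at n = 5
  cmp_s <- compare_groups(ft, unit_level = "subject")
  expect_gte(cmp_s$p_raw[cmp_s$group == "NR"], 1 / choose(10, 5) * 2)
})

test_that("identical pre/post distributions stay null under FDR", {
  n_sig <- vapply(1:30, function(k) {
    ft <- make_feature_frame(shift_nr_offset = 0, seed = 100 + k)
    sum(compare_groups(ft)$significant)
  }, 0L)
  # false-discovery proportion over all families within Monte-Carlo error
  rate <- sum(n_sig) / (30 * 2)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("correlate_with_outcome recovers a linear variation-outcome link", {
  set.seed(75)
  labar <- c(runif(5, 55, 100), runif(5, -10, 45))
  clinical <- data.frame(subject = sprintf("S%02d", 1:10), labar = labar)
  rows <- list()
  for (i in 1:10) for (sess in c("pre", "post")) {
    base <- 2
    val <- base + (sess == "post") * (-0.004 * labar[i] + rnorm(1, 0, 0.01)) +
      rnorm(20, 0, 0.02)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sprintf("S%02d", i), group = "R", session = sess,
      measure = "aperiodic", feature = "exponent", scale = "global",
      unit = NA_character_, epoch = 1:20, value = val,
      stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, rows)
  res <- correlate_with_outcome(ft, clinical)
  expect_lt(res$rho, -0.8)
  expect_lt(res$p, 0.05)
  expect_identical(res$n, 10L)
})

test_that("variation independent of outcome rarely flags significance", {
  set.seed(76)
  hits <- vapply(1:200, function(k) {
    rv <- rnorm(10)
    lab <- runif(10, -10, 100)
    spearman_rho(rv, lab)$p <= 0.05
  }, NA)
  expect_gte(mean(!hits), 0.90)
})

test_that("outcome correlation works at the minimal n = 3", {
  clinical <- data.frame(subject = c("a", "b", "c"), labar = c(10, 50, 90))
  rows <- do.call(rbind, lapply(c("a", "b", "c"), function(s) {
    do.call(rbind, lapply(c("pre", "post"), function(sess)
      data.frame(subject = s, group = "R", session = sess, measure = "pli",
                 feature = "alpha", scale = "global", unit = NA_character_,
                 epoch = 1:5,
                 value = stats::runif(5) + (sess == "post") * match(s, c("a", "b", "c")),
                 stringsAsFactors = FALSE)))
  }))
  res <- correlate_with_outcome(rows, clinical)
  expect_identical(nrow(res), 1L)
  expect_true(is.finite(res$rho))
})
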
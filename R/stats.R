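# Nonparametric statistics for pre/post comparisons within responder groups,
# FDR families per spatial subdivision, effect sizes, the Labar seizure-
# reduction index, and correlation of feature variation with outcome.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test via [stats::wilcox.test()]: exact enumeration for small
#' tie-free samples (both n <= 8), tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `U` (statistic for `x`), `p` (two-sided), and `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced) via
#' [stats::p.adjust()]; the significance mask compares the adjusted values
#' to `alpha`.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_adjusted` and `significant` (logical).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.04, 0.60))$p_adjusted
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stopf("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj < alpha)
}

#' Cohen's d with pooled standard deviation
#'
#' `|mean(x) - mean(y)| / s_pooled`,
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return Nonnegative scalar; `NaN` (with a warning) if the pooled SD is 0.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stopf("need >= 2 values per sample")
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    warnf("zero pooled SD: Cohen's d undefined")
    return(NaN)
  }
  abs(mean(x) - mean(y)) / sp
}

#' Relative variation of a feature (post vs pre medians)
#'
#' `(median(post) - median(pre)) / median(pre)`.
#'
#' @param pre_values,post_values Nonempty numeric vectors.
#' @return Scalar; `NaN` (with a warning) when the pre median is 0.
#' @export
relative_variation <- function(pre_values, post_values) {
  if (!length(pre_values) || !length(post_values))
    stopf("both samples must be nonempty")
  m0 <- stats::median(pre_values)
  if (m0 == 0) {
    warnf("zero pre-implant median: relative variation undefined")
    return(NaN)
  }
  (stats::median(post_values) - m0) / m0
}

#' Labar seizure-reduction index
#'
#' Minus the percentage change in monthly seizure frequency:
#' `-100 * (post - pre) / pre`. Positive values mean improvement; 100 means
#' seizure freedom. Both rates zero is defined as 0.
#'
#' @param pre_rate,post_rate Seizures/month, >= 0 (vectorized).
#' @return Index in percent; `NaN` (with a warning) where `pre_rate` is 0
#'   with a positive `post_rate`.
#' @examples
#' labar_index(11.80, 11.25)
#' labar_index(0.13, 0)
#' @export
labar_index <- function(pre_rate, post_rate) {
  if (any(pre_rate < 0 | post_rate < 0)) stopf("rates must be >= 0")
  out <- -100 * (post_rate - pre_rate) / pre_rate
  both0 <- pre_rate == 0 & post_rate == 0
  out[both0] <- 0
  undef <- pre_rate == 0 & post_rate > 0
  if (any(undef)) {
    warnf("pre-implant rate 0 with nonzero post rate: index undefined")
    out[undef] <- NaN
  }
  out
}

#' Classify clinical response from the Labar index
#'
#' Responder (`"R"`) iff the index is at least 50 (a seizure reduction of at
#' least 50\%). The frequency-computable outcome bucket is `"I"` for >= 80,
#' `"II"` for 50-80, `"other"` below 50 (the finer outcome classes below 50
#' require non-frequency clinical information).
#'
#' @param labar Labar index (percent), finite; vectorized.
#' @return Data frame with `group` (`"R"`/`"NR"`) and `bucket`
#'   (`"I"`/`"II"`/`"other"`).
#' @examples
#' classify_responder(c(85.67, 4.66, 50))
#' @export
classify_responder <- function(labar) {
  if (any(!is.finite(labar))) stopf("labar must be finite")
  data.frame(
    group = ifelse(labar >= 50, "R", "NR"),
    bucket = ifelse(labar >= 80, "I", ifelse(labar >= 50, "II", "other")),
    stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of (mid-)ranks via [stats::cor.test()]: exact p for
#' small tie-free samples, t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("lengths differ")
  if (length(x) < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: Spearman correlation undefined")
    return(list(rho = NaN, p = NaN))
  }
  no_ties <- !(anyDuplicated(x) || anyDuplicated(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) <= 10L && no_ties))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Group FDR-correction families
#'
#' Tests are corrected in the family structure of the analysis: for PLI, all
#' frequency-band tests within one spatial subdivision (and group) form a
#' family — per region at the regional scale, all channels x bands together
#' at the channel scale (set `channel_family = "per_region"` for per-region
#' channel families instead); for aperiodic parameters, the offset and
#' exponent tests within one subdivision form the family.
#'
#' @param results Data frame with at least `measure` (`"pli"`/`"aperiodic"`),
#'   `group`, `scale` (`"global"`/`"regional"`/`"channel"`), and `unit`
#'   (region or channel name, `NA` for global).
#' @param channel_family `"pooled"` (default) or `"per_region"`.
#' @param montage Montage used to map channels to regions when
#'   `channel_family = "per_region"`.
#' @return Character vector of family identifiers, one per row.
#' @export
build_fdr_families <- function(results, channel_family = c("pooled",
                                                           "per_region"),
                               montage = default_montage()) {
  channel_family <- match.arg(channel_family)
  need <- c("measure", "group", "scale", "unit")
  if (!all(need %in% names(results)))
    stopf("results must have columns: %s", paste(need, collapse = ", "))
  sub <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    sc <- results$scale[i]
    sub[i] <- switch(sc,
      global = "global",
      regional = paste0("region:", results$unit[i]),
      channel = if (channel_family == "pooled") "channels" else
        paste0("channels:", montage$region[[results$unit[i]]]),
      stopf("unknown scale '%s'", sc))
  }
  paste(results$measure, results$group, sub, sep = "|")
}

#' Pre- vs post-implant group comparisons with FDR families
#'
#' For every feature (measure x band/parameter x scale x unit) and group,
#' compares the epoch-level pre and post distributions with the Mann-Whitney
#' U test, adjusts p-values by Benjamini-Hochberg within the
#' [build_fdr_families()] structure, and reports descriptives, Cohen's d and
#' the trend (sign of the post-pre median difference, reported only for
#' significant tests).
#'
#' By default epoch-level values are pooled across a group's subjects (the
#' epoch is the statistical unit); `unit_level = "subject"` instead reduces
#' each subject's epochs to their median first. The pooled default is the
#' only unit that can reach very small p-values at 5 subjects per group, and
#' is flagged here as the analysis' key ambiguity.
#'
#' @param features Data frame with columns `subject`, `group`, `session`
#'   (`"pre"`/`"post"`), `measure`, `feature` (band or parameter name),
#'   `scale`, `unit`, `epoch`, `value` (see [extract_features()]).
#' @param alpha Significance level (default 0.05).
#' @param unit_level `"epoch"` (pooled, default) or `"subject"`.
#' @param channel_family,montage Passed to [build_fdr_families()].
#' @return Data frame (class `comparison_table`) with one row per feature x
#'   group: `p_raw`, `p_fdr`, `significant`, `trend`, `mean_pre`, `sd_pre`,
#'   `mean_post`, `sd_post`, `cohens_d`.
#' @export
compare_groups <- function(features, alpha = 0.05,
                           unit_level = c("epoch", "subject"),
                           channel_family = "pooled",
                           montage = default_montage()) {
  unit_level <- match.arg(unit_level)
  need <- c("subject", "group", "session", "measure", "feature", "scale",
            "unit", "epoch", "value")
  if (!all(need %in% names(features)))
    stopf("features must have columns: %s", paste(need, collapse = ", "))
  if (!all(c("pre", "post") %in% features$session))
    stopf("need both pre and post sessions")

  key <- paste(features$measure, features$feature, features$scale,
               ifelse(is.na(features$unit), "", features$unit),
               features$group, sep = "|")
  rows <- lapply(split(seq_len(nrow(features)), key), function(idx) {
    ft <- features[idx, ]
    pull <- function(sess) {
      v <- ft[ft$session == sess, ]
      if (unit_level == "subject")
        as.numeric(tapply(v$value, v$subject, stats::median))
      else v$value
    }
    x_pre <- pull("pre"); x_post <- pull("post")
    if (!length(x_pre) || !length(x_post)) return(NULL)
    mw <- mann_whitney_u(x_pre, x_post)
    data.frame(
      measure = ft$measure[1L], feature = ft$feature[1L],
      scale = ft$scale[1L], unit = ft$unit[1L], group = ft$group[1L],
      p_raw = mw$p,
      mean_pre = mean(x_pre), sd_pre = stats::sd(x_pre),
      mean_post = mean(x_post), sd_post = stats::sd(x_post),
      median_diff = stats::median(x_post) - stats::median(x_pre),
      cohens_d = cohens_d(x_pre, x_post),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  fam <- build_fdr_families(out, channel_family = channel_family,
                            montage = montage)
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    i <- fam == f
    out$p_fdr[i] <- fdr_bh(out$p_raw[i], alpha)$p_adjusted
  }
  out$significant <- out$p_fdr < alpha
  out$trend <- ifelse(!out$significant, "none",
                      ifelse(out$median_diff > 0, "up",
                             ifelse(out$median_diff < 0, "down", "none")))
  out$family <- fam
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, max_rows = 20L, ...) {
  cat(sprintf("<comparison_table> %d tests, %d significant (FDR)\n",
              nrow(x), sum(x$significant)))
  sig <- x[x$significant, c("measure", "feature", "scale", "unit", "group",
                            "p_raw", "p_fdr", "trend", "cohens_d")]
  if (nrow(sig)) {
    cat("significant tests:\n")
    print.data.frame(utils::head(sig, max_rows), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Correlate per-subject feature variation with clinical outcome
#'
#' For each feature, computes each subject's relative variation
#' ([relative_variation()] of post vs pre epoch-level medians) and its
#' Spearman correlation with the subject's Labar index across the whole
#' cohort.
#'
#' @param features Feature table (see [compare_groups()]).
#' @param clinical Data frame with `subject` (or `id`) and `labar`.
#' @param scale Spatial scale to correlate at (default `"global"`, the scale
#'   the outcome analysis reports).
#' @return Data frame with `measure`, `feature`, `rho`, `p`, `n`.
#' @export
correlate_with_outcome <- function(features, clinical, scale = "global") {
  if ("id" %in% names(clinical) && !"subject" %in% names(clinical))
    names(clinical)[names(clinical) == "id"] <- "subject"
  ft <- features[features$scale == scale, ]
  key <- interaction(ft$measure, ft$feature, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(ft)), key), function(idx) {
    v <- ft[idx, ]
    subs <- intersect(unique(v$subject), clinical$subject)
    rv <- vapply(subs, function(s) {
      relative_variation(v$value[v$subject == s & v$session == "pre"],
                         v$value[v$subject == s & v$session == "post"])
    }, 0)
    ok <- is.finite(rv)
    if (sum(ok) < 3L) return(NULL)
    lab <- clinical$labar[match(subs[ok], clinical$subject)]
    sr <- spearman_rho(rv[ok], lab)
    data.frame(measure = v$measure[1L], feature = v$feature[1L],
               rho = sr$rho, p = sr$p, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clinical table of the ten-patient reference cohort
#'
#' The published per-patient monthly seizure frequencies before and after
#' implantation, ages, printed Labar indices and outcome classes of the
#' ten-subject VNS cohort this package's analysis design follows. Used as a
#' worked example and as the input for the clinical-arithmetic checks.
#'
#' @return Data frame with `id`, `age`, `pre_rate`, `post_rate`,
#'   `labar_printed`, `mchugh_class`.
#' @examples
#' tab <- vns_example_cohort()
#' labar_index(tab$pre_rate, tab$post_rate)
#' @export
vns_example_cohort <- function() {
  data.frame(
    id = 1:10,
    age = c(45, 31, 48, 61, 42, 46, 35, 34, 50, 27),
    pre_rate = c(11.80, 43.70, 3.00, 20.00, 4.00, 0.13, 0.33, 10.00,
                 2.00, 33.00),
    post_rate = c(11.25, 47.40, 0.43, 0.10, 0.67, 0.00, 0.33, 10.00,
                  2.00, 8.40),
    labar_printed = c(4.66, -8.47, 85.67, 99.50, 83.25, 100.00, 0.00,
                      0.00, 0.00, 72.00),
    mchugh_class = c("III A", "III B", "I B", "I A", "I B", "I A",
                     "III B", "V", "III A", "II A"),
    stringsAsFactors = FALSE)
}
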
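# End-to-end orchestration: cohort -> band stack -> PLI + aperiodic feature
# tables -> group statistics and outcome correlation, with a provenance
# manifest. Every stage is also callable on its own.

#' Extract the epoch-level feature table of a cohort
#'
#' For every subject and session: common-average reference, five-band
#' decomposition, PLI at the global / regional / channel scales per band, and
#' aperiodic offset / exponent (broadband Welch + robust fit) at the same
#' scales. Returns the long table that [compare_groups()] and
#' [correlate_with_outcome()] consume; the epoch-level values are retained
#' throughout.
#'
#' @param cohort A `vns_cohort` (or list of subjects shaped like one).
#' @param montage Montage; default built from the first subject's labels.
#' @param fit_range Aperiodic fit range (Hz).
#' @param verbose Print per-subject progress.
#' @return Data frame with columns `subject`, `group`, `session`, `measure`,
#'   `feature`, `scale`, `unit`, `epoch`, `value`.
#' @export
extract_features <- function(cohort, montage = NULL, fit_range = c(1, 40),
                             verbose = FALSE) {
  subjects <- if (inherits(cohort, "vns_cohort")) cohort$subjects else cohort
  if (is.null(montage))
    montage <- montage(subjects[[1L]]$pre$channel_labels)
  out <- vector("list", 2L * length(subjects))
  k <- 0L
  for (s in subjects) {
    for (sess in c("pre", "post")) {
      if (verbose) message(sprintf("features: %s %s", s$id, sess))
      ep <- s[[sess]]
      stack <- extract_band_stack(ep, expected_channels = n_channels(ep))
      conn <- pli_connectivity(stack, montage)
      ap <- aperiodic_per_epoch(attr(stack, "broadband"), fit_range)
      agg <- aggregate_aperiodic(ap, montage)
      k <- k + 1L
      out[[k]] <- rbind(.pli_rows(conn, s, sess), .ap_rows(ap, agg, s, sess))
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

.feature_row <- function(s, sess, measure, feature, scale, unit, values) {
  data.frame(subject = s$id, group = s$group, session = sess,
             measure = measure, feature = feature, scale = scale,
             unit = unit, epoch = seq_along(values), value = as.numeric(values),
             stringsAsFactors = FALSE)
}

.pli_rows <- function(conn, s, sess) {
  rows <- list()
  for (b in names(conn$global)) {
    rows <- c(rows, list(
      .feature_row(s, sess, "pli", b, "global", NA_character_,
                   conn$global[[b]])))
    reg <- conn$regional[[b]]
    for (r in colnames(reg)) if (!anyNA(reg[, r]))
      rows <- c(rows, list(.feature_row(s, sess, "pli", b, "regional", r,
                                        reg[, r])))
    ch <- conn$channel[[b]]
    for (cc in colnames(ch))
      rows <- c(rows, list(.feature_row(s, sess, "pli", b, "channel", cc,
                                        ch[, cc])))
  }
  do.call(rbind, rows)
}

.ap_rows <- function(ap, agg, s, sess) {
  rows <- list()
  for (q in c("offset", "exponent")) {
    rows <- c(rows, list(
      .feature_row(s, sess, "aperiodic", q, "global", NA_character_,
                   agg[[q]]$global)))
    reg <- agg[[q]]$regional
    for (r in colnames(reg)) if (!anyNA(reg[, r]))
      rows <- c(rows, list(.feature_row(s, sess, "aperiodic", q, "regional",
                                        r, reg[, r])))
    m <- ap[[q]]
    for (cc in colnames(m))
      rows <- c(rows, list(.feature_row(s, sess, "aperiodic", q, "channel",
                                        cc, m[, cc])))
  }
  do.call(rbind, rows)
}

#' Run configuration
#'
#' @param cohort_spec A [cohort_spec()] describing the synthetic cohort to
#'   simulate, or `NULL` when `cohort` is supplied.
#' @param cohort An existing `vns_cohort` (takes precedence).
#' @param alpha Significance level in `(0, 1)`.
#' @param unit_level,channel_family Passed to [compare_groups()].
#' @param fit_range Aperiodic fit range (Hz).
#' @param out_dir Output directory for CSV tables and the manifest, or
#'   `NULL` to skip writing.
#' @param seed Overrides the cohort spec's seed when given.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_spec = NULL, cohort = NULL, alpha = 0.05,
                       unit_level = "epoch", channel_family = "pooled",
                       fit_range = c(1, 40), out_dir = NULL, seed = NULL) {
  structure(list(cohort_spec = cohort_spec, cohort = cohort, alpha = alpha,
                 unit_level = unit_level, channel_family = channel_family,
                 fit_range = fit_range, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks alpha, the fit range against Nyquist, band sanity, montage
#' coverage of coupling specs, and group sizes; errors are aggregated.
#'
#' @param config A [run_config()] (or [cohort_spec()]).
#' @return `TRUE` invisibly if valid, otherwise stops with the full list.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(e) errs <<- c(errs, e)
  if (inherits(config, "cohort_spec"))
    config <- run_config(cohort_spec = config)
  if (!is.null(config$alpha) &&
      (config$alpha <= 0 || config$alpha >= 1))
    push(sprintf("alpha must be in (0, 1), got %g", config$alpha))
  if (!is.null(config$unit_level) &&
      !config$unit_level %in% c("epoch", "subject"))
    push(sprintf("unknown unit_level '%s'", config$unit_level))
  cs <- config$cohort_spec
  if (!is.null(cs)) {
    if (cs$n_responders < 1L || cs$n_nonresponders < 1L)
      push("both groups need at least one subject")
    nyq <- cs$fs / 2
    top <- max(band_definitions()$high + band_definitions()$transition_high)
    if (top > nyq)
      push(sprintf("band stack needs fs >= %g Hz (got %g)", 2 * top, cs$fs))
    if (!is.null(config$fit_range) && config$fit_range[2L] > nyq)
      push(sprintf("fit range upper edge %g Hz above Nyquist %g Hz",
                   config$fit_range[2L], nyq))
    bad <- setdiff(names(cs$feature_shift$pli$R), .band_names)
    if (length(bad))
      push(sprintf("unknown band name(s) in feature_shift: %s",
                   paste(bad, collapse = ", ")))
    reg <- region_of_label(normalize_channel_labels(cs$channel_labels))
    if (anyNA(reg))
      push(sprintf("channel(s) without region: %s",
                   paste(cs$channel_labels[is.na(reg)], collapse = ", ")))
  } else if (is.null(config$cohort)) {
    push("config needs either a cohort_spec or a cohort")
  }
  if (length(errs))
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' Run the full analysis
#'
#' simulate (unless a cohort is given) -> preprocess -> PLI + aperiodic
#' features -> group comparisons and outcome correlation. Deterministic
#' under a fixed seed. When `out_dir` is set, writes `cohort.csv`,
#' `features.csv`, `comparisons.csv`, `correlations.csv` and
#' `manifest.json`-style provenance (`manifest.txt` with config snapshot and
#' per-file MD5 checksums).
#'
#' @param config A [run_config()] (or a bare [cohort_spec()]).
#' @param verbose Progress messages.
#' @return Object of class `vns_study`: list with `cohort_table`,
#'   `features`, `comparisons`, `correlations`, `config`, `manifest`.
#' @export
run_full <- function(config, verbose = FALSE) {
  if (inherits(config, "cohort_spec"))
    config <- run_config(cohort_spec = config)
  validate_config(config)
  cohort <- config$cohort
  if (is.null(cohort)) {
    cs <- config$cohort_spec
    if (!is.null(config$seed)) cs$seed <- config$seed
    if (verbose) message("stage simulate: generating cohort")
    cohort <- generate_cohort(cs, verbose = verbose)
  }
  mt <- montage(cohort$subjects[[1L]]$pre$channel_labels)
  if (verbose) message("stage features: PLI + aperiodic extraction")
  features <- extract_features(cohort, mt, config$fit_range,
                               verbose = verbose)
  if (verbose) message("stage stats: group comparisons + correlation")
  comparisons <- compare_groups(features, alpha = config$alpha,
                                unit_level = config$unit_level,
                                channel_family = config$channel_family,
                                montage = mt)
  clin <- cohort_table(cohort)
  correlations <- correlate_with_outcome(features, clin)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(wr(clin, "cohort.csv"), wr(features, "features.csv"),
               wr(comparisons, "comparisons.csv"),
               wr(correlations, "correlations.csv"))
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    mf <- file.path(config$out_dir, "manifest.txt")
    writeLines(c(
      sprintf("vnseeg %s", as.character(utils::packageVersion("vnseeg"))),
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      sprintf("alpha=%g unit_level=%s channel_family=%s fit_range=%g-%g",
              config$alpha, config$unit_level, config$channel_family,
              config$fit_range[1L], config$fit_range[2L]),
      sprintf("%s  %s", manifest$md5, manifest$file)), mf)
  }
  structure(list(cohort_table = clin, features = features,
                 comparisons = comparisons, correlations = correlations,
                 config = config, manifest = manifest),
            class = "vns_study")
}

#' @export
print.vns_study <- function(x, ...) {
  cat(sprintf("<vns_study> %d subjects, %d feature tests, %d significant\n",
              nrow(x$cohort_table), nrow(x$comparisons),
              sum(x$comparisons$significant)))
  invisible(x)
}

#' @export
summary.vns_study <- function(object, ...) {
  cat("Cohort\n------\n")
  print.data.frame(object$cohort_table, digits = 4, row.names = FALSE)
  cat("\nGroup comparisons (global scale)\n--------------------------------\n")
  g <- object$comparisons[object$comparisons$scale == "global",
                          c("measure", "feature", "group", "p_raw", "p_fdr",
                            "trend", "mean_pre", "mean_post", "cohens_d")]
  print.data.frame(g, digits = 3, row.names = FALSE)
  cat("\nCorrelation with the Labar index (global)\n")
  cat("-----------------------------------------\n")
  print.data.frame(object$correlations, digits = 3, row.names = FALSE)
  invisible(object)
}
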
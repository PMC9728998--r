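# Synthetic clinical cohorts: paired pre/post epoch sets per subject with
# known group-level ground truth in PLI and aperiodic parameters, plus
# seizure diaries yielding a spread of Labar indices.

# default 19-channel 10-20 subset used by the desk-scale cohort world:
# every region keeps >= 2 channels
.cohort_labels_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                       "T7", "C3", "Cz", "C4", "T8",
                       "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

# analytic in-band power (uV^2) of a 10^offset / f^exponent spectrum
.band_power <- function(offset, exponent, lo, hi) {
  if (abs(exponent - 1) < 1e-9) return(10^offset * log(hi / lo))
  10^offset * (hi^(1 - exponent) - lo^(1 - exponent)) / (1 - exponent)
}

#' Default ground-truth feature shifts for a synthetic cohort
#'
#' Signed pre->post changes mirroring the directions and magnitudes of the
#' reference study's group-level findings: responders' global PLI falls in
#' delta and gamma and rises in alpha while offset and exponent fall by 0.1;
#' non-responders' offset and exponent rise by 0.2 with no PLI change.
#' PLI shifts are expressed as the change in expected pair-PLI on the
#' designated coupled pairs.
#'
#' @return Nested list with `aperiodic` (per parameter, per group scalar
#'   shifts) and `pli` (per group, per band signed pair-PLI shifts).
#' @export
default_feature_shift <- function() {
  list(
    aperiodic = list(
      offset = c(R = -0.1, NR = 0.2),
      exponent = c(R = -0.1, NR = 0.2)
    ),
    pli = list(
      R = c(delta = -0.30, alpha = 0.30, gamma = -0.30),
      NR = c()
    )
  )
}

#' Cohort specification
#'
#' Describes a two-group (responder / non-responder) cohort with seizure
#' diaries and ground-truth EEG feature shifts. Reduction ranges must respect
#' the 50\% responder threshold: a responder's seizure reduction fraction is
#' drawn from `responder_reduction_range` (within `[0.5, 1]`, so the Labar
#' index lands in `[50, 100]`), a non-responder's from
#' `nonresponder_reduction_range` (upper end < 0.5).
#'
#' The EEG world is desk-scale by default: 19 channels (10-20 subset),
#' 128 Hz, the reference 20 epochs of 8 s, so a full cohort fits comfortably
#' in memory and CPU budget; epoch count and length are the reference
#' acquisition's, and the band-time products that set PLI estimator noise
#' are unchanged by the reduced sampling rate.
#'
#' @param n_responders,n_nonresponders Group sizes (>= 1).
#' @param pre_rate_meanlog,pre_rate_sdlog Log-normal parameters of the
#'   pre-implant monthly seizure rate (defaults give a realistic spread of
#'   roughly 0.5-50 seizures/month).
#' @param responder_reduction_range Numeric length 2 within `[0.5, 1]`.
#' @param nonresponder_reduction_range Numeric length 2 with max < 0.5
#'   (negative values = seizure increase).
#' @param feature_shift See [default_feature_shift()].
#' @param labar_coupling If `TRUE` (default) each subject's aperiodic shift
#'   keeps the group's sign but its magnitude scales (0.5x-1.5x) with the
#'   subject's position inside the group's Labar range, so the relative
#'   variation is negatively monotone in clinical response across the cohort;
#'   if `FALSE` shifts are constant per group.
#' @param baseline_offset,baseline_exponent Group-mean pre-implant aperiodic
#'   parameters (defaults 1.4 and 2.0).
#' @param subject_sd Between-subject SD of the aperiodic baselines
#'   (default 0.1; deliberately modest so ground truth is recoverable at
#'   n = 5 per group).
#' @param pli_pair_base Expected pair-PLI of coupled pairs before implant
#'   (default 0.35).
#' @param n_coupled_pairs Coupled channel pairs per shifted band (default 10).
#' @param channel_labels,fs,epoch_seconds,n_epochs,leakage EEG world
#'   parameters (see [sim_config()]).
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 5L, n_nonresponders = 5L,
                        pre_rate_meanlog = log(5), pre_rate_sdlog = 1.2,
                        responder_reduction_range = c(0.5, 1),
                        nonresponder_reduction_range = c(-0.15, 0.45),
                        feature_shift = default_feature_shift(),
                        labar_coupling = TRUE,
                        baseline_offset = 1.4, baseline_exponent = 2.0,
                        subject_sd = 0.1,
                        pli_pair_base = 0.35, n_coupled_pairs = 10L,
                        channel_labels = .cohort_labels_19,
                        fs = 128, epoch_seconds = 8, n_epochs = 20L,
                        leakage = 0.2, seed = 1L) {
  if (n_responders < 1L || n_nonresponders < 1L)
    stopf("both groups need at least one subject")
  rr <- responder_reduction_range
  nr <- nonresponder_reduction_range
  if (rr[1L] < 0.5 || rr[2L] > 1 || rr[1L] > rr[2L])
    stopf("responder_reduction_range must lie within [0.5, 1]")
  if (max(nr) >= 0.5)
    stopf("nonresponder_reduction_range must stay below the 0.5 threshold")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic responder / non-responder cohort
#'
#' Draws each subject's seizure diary (pre rate, reduction fraction, hence
#' post rate and Labar index), then simulates paired pre/post epoch sets:
#' per-channel 1/f^chi backgrounds at the subject's baseline aperiodic
#' parameters (shifted post-implant by the group's — or Labar-interpolated —
#' ground truth), band-limited coupled oscillations on randomly chosen
#' channel pairs whose von Mises concentration is set by inverting
#' [expected_pli()] to hit the target pair-PLI pre and post, and zero-lag
#' mixing. Deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param verbose Print per-subject progress.
#' @return Object of class `vns_cohort`: list with `subjects` (each: `id`,
#'   `group`, `pre_rate`, `post_rate`, `labar`, `pre`/`post` [eeg_epochs],
#'   `truth` list of injected shifts) and the `spec`.
#' @export
generate_cohort <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  ns_total <- spec$n_responders + spec$n_nonresponders
  shifts <- spec$feature_shift

  with_seed(spec$seed, {
    groups <- rep(c("R", "NR"), c(spec$n_responders, spec$n_nonresponders))
    pre_rate <- stats::rlnorm(ns_total, spec$pre_rate_meanlog,
                              spec$pre_rate_sdlog)
    red <- ifelse(groups == "R",
                  stats::runif(ns_total, spec$responder_reduction_range[1L],
                               spec$responder_reduction_range[2L]),
                  stats::runif(ns_total,
                               spec$nonresponder_reduction_range[1L],
                               spec$nonresponder_reduction_range[2L]))
    post_rate <- pre_rate * (1 - red)
    labar <- 100 * red

    # per-band coupling kappas: solved once from the pair-PLI targets
    kappa_cache <- new.env()
    kappa_of <- function(target) {
      key <- sprintf("%.6f", target)
      if (is.null(kappa_cache[[key]]))
        kappa_cache[[key]] <- .kappa_for_pli(max(target, 0.02))
      kappa_cache[[key]]
    }

    subjects <- vector("list", ns_total)
    for (i in seq_len(ns_total)) {
      g <- groups[i]
      # subject aperiodic baselines (channel-common part)
      off_i <- stats::rnorm(1L, spec$baseline_offset, spec$subject_sd)
      exp_i <- max(0.1, stats::rnorm(1L, spec$baseline_exponent,
                                     spec$subject_sd / 2))
      # every subject keeps the group's shift sign; under labar_coupling the
      # magnitude scales 0.5x-1.5x with the subject's position inside the
      # group's Labar range, making the shift monotone in clinical outcome
      # across the cohort without ever flipping a group's direction
      rng <- 100 * (if (g == "R") spec$responder_reduction_range
                    else spec$nonresponder_reduction_range)
      pos <- if (diff(rng) < 1e-9) 0.5
             else (labar[i] - rng[1L]) / diff(rng)
      ap_shift <- vapply(c("offset", "exponent"), function(q) {
        tg <- shifts$aperiodic[[q]]
        if (!spec$labar_coupling) return(tg[[g]])
        if (g == "R") tg[["R"]] * (0.5 + pos)       # deeper response, larger drop
        else tg[["NR"]] * (1.5 - pos)               # poorer response, larger rise
      }, 0)

      # coupled pairs per shifted band (same pairs pre and post); the
      # oscillation amplitude is set to 3x the background's in-band RMS so
      # the observed pair-PLI sits close to the von Mises target
      band_shift <- shifts$pli[[g]]
      couplings <- list(pre = list(), post = list())
      for (b in names(band_shift)) {
        bd <- band_definitions(b)
        amp <- 3 * sqrt(.band_power(off_i, exp_i, bd$low, bd$high))
        pick <- replicate(spec$n_coupled_pairs,
                          sample(spec$channel_labels, 2L), simplify = FALSE)
        tgt_pre <- spec$pli_pair_base
        tgt_post <- min(0.95, max(0.02, tgt_pre + band_shift[[b]]))
        for (pr in pick) {
          couplings$pre <- c(couplings$pre, list(coupling_spec(
            pr, b, lag_delta = pi / 4, jitter_kappa = kappa_of(tgt_pre),
            amplitude = amp)))
          couplings$post <- c(couplings$post, list(coupling_spec(
            pr, b, lag_delta = pi / 4, jitter_kappa = kappa_of(tgt_post),
            amplitude = amp)))
        }
      }

      make_session <- function(session) {
        shift_on <- session == "post"
        ap <- lapply(seq_along(spec$channel_labels), function(ch)
          aperiodic_spec(
            off_i + stats::rnorm(1L, 0, 0.02) +
              if (shift_on) ap_shift[["offset"]] else 0,
            max(0.05, exp_i + stats::rnorm(1L, 0, 0.02) +
              if (shift_on) ap_shift[["exponent"]] else 0)))
        cfg <- sim_config(
          fs = spec$fs, epoch_seconds = spec$epoch_seconds,
          n_epochs = spec$n_epochs, aperiodic = ap,
          couplings = couplings[[session]], leakage = spec$leakage,
          channel_labels = spec$channel_labels,
          seed = sample.int(.Machine$integer.max, 1L))
        generate_epoch_set(cfg, subject_id = sprintf("S%02d", i),
                           session = session)
      }
      if (verbose) message(sprintf("subject %d/%d (%s)", i, ns_total, g))
      subjects[[i]] <- list(
        id = sprintf("S%02d", i), group = g,
        pre_rate = pre_rate[i], post_rate = post_rate[i], labar = labar[i],
        pre = make_session("pre"), post = make_session("post"),
        truth = list(aperiodic_shift = ap_shift, pli_shift = band_shift))
    }
    structure(list(subjects = subjects, spec = spec), class = "vns_cohort")
  })
}

#' @export
print.vns_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, "", "group")
  lab <- vapply(x$subjects, `[[`, 0, "labar")
  cat(sprintf("<vns_cohort> %d subjects (%d R, %d NR)\n",
              length(g), sum(g == "R"), sum(g == "NR")))
  cat(sprintf("  Labar index: %s\n",
              paste(sprintf("%.1f", lab), collapse = ", ")))
  invisible(x)
}

#' Cohort clinical table
#'
#' @param cohort A `vns_cohort`.
#' @return Data frame with `id`, `group`, `pre_rate`, `post_rate`, `labar`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "vns_cohort"))
  data.frame(
    id = vapply(cohort$subjects, `[[`, "", "id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    pre_rate = vapply(cohort$subjects, `[[`, 0, "pre_rate"),
    post_rate = vapply(cohort$subjects, `[[`, 0, "post_rate"),
    labar = vapply(cohort$subjects, `[[`, 0, "labar"),
    stringsAsFactors = FALSE)
}
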
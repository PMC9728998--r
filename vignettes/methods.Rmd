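---
title: "Methods: PLI connectivity and aperiodic spectral parameters in VNS outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity and aperiodic spectral parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnseeg)
```

## The analysis problem

Vagus nerve stimulation (VNS) is a neuromodulation therapy for drug-resistant
epilepsy. Roughly half of implanted patients respond (a reduction of at least
50% in monthly seizure frequency); there is no accepted pre- or
post-implantation EEG biomarker of response. This package implements a
resting-EEG analysis designed for that question: phase lag index (PLI)
functional connectivity in the five classical frequency bands, and the two
parameters of the aperiodic (1/f-like) spectral component, each compared
before versus after implantation within responder and non-responder groups,
and each correlated with the clinical outcome as quantified by the Labar
index.

The reference acquisition is 61 scalp channels in the International 10–10
layout, sampled at 1,024 Hz and bandpass filtered 0.5–70 Hz, from which 20
artifact-free epochs of 8 s (8,192 samples) are selected per session. Because
clinical recordings of this kind are not redistributable, the package ships a
synthetic-EEG cohort generator with fully known ground truth; every stage of
the pipeline is validated against that ground truth or against closed-form
oracles.

## Preprocessing

Epochs are first re-referenced to the common average over all scalp channels
(`common_average_reference()`), which makes the instantaneous channel mean
exactly zero and is idempotent. Band decomposition then uses zero-phase
frequency-domain filters (`apply_band_filter()`): the epoch's spectrum is
multiplied by a real magnitude response and inverse-transformed, so no phase
distortion is introduced — essential for a phase-based connectivity metric.

The five bands are delta 0.5–3 Hz, theta 3–8 Hz, alpha 8–12 Hz, beta
12–30 Hz, and gamma 30–50 Hz, with transition widths of 1/2, 2/3, 3/4, 4/5,
and 3/3 Hz on the low/high side respectively. Design choices the band
specification leaves open, and how they were fixed:

* **Transition shape.** Unspecified; a raised-cosine magnitude taper is used
  (smooth, standard, fully determined by the stated widths; the transition
  midpoint has gain 0.5).
* **Transition placement.** Transitions extend *outward* from the stated
  cut-offs, so the printed passband is passed at unit gain (e.g. delta is
  fully stopped at 3 + 2 = 5 Hz).
* **The delta low edge.** A 1 Hz transition below the 0.5 Hz cut-off would
  cross 0 Hz; the low transition is clamped at 0 Hz. Epochs are demeaned
  before filtering, so the DC bin is zero regardless.
* **Epoch independence.** Epochs are non-contiguous selections, so they are
  filtered independently with no cross-epoch continuity and no extra edge
  taper by default (at 8 s the edge transients are small relative to the
  bands of interest).

The broadband signal used for aperiodic fitting is the re-referenced,
*unfiltered* signal (beyond the acquisition bandpass), not a band output.

## Phase lag index

For two narrowband signals with instantaneous phases `phi_a(t)`, `phi_b(t)`
(arguments of the analytic signal, `instantaneous_phase()`),

    PLI = | mean_t sign( wrap(phi_a(t) - phi_b(t)) ) |

with the difference wrapped to (−pi, pi] and `sign(0) = 0`. PLI is 0 when
the phase-difference distribution is symmetric about zero (no coupling, or
purely instantaneous coupling) and 1 for a perfectly consistent nonzero lag.
Because volume conduction spreads sources to multiple sensors with *zero*
lag, exactly-zero phase differences carry no weight, which is why PLI is the
connectivity measure of choice on scalp data.

Aggregation follows the analysis design at three spatial scales, computed
per epoch and per band so the epoch-level distributions remain available to
the statistics:

* **global** — mean over all unordered channel pairs;
* **regional** — mean over pairs with both members inside one scalp region
  (frontal, temporal, central, parietal, occipital);
* **channel** — mean over all pairs involving the channel.

The mean of the channel values equals the global value exactly (every pair
appears twice in both numerator and denominator); this identity is tested.

The electrode-to-region map is a prefix rule (Fp/AF/F frontal, FT/T/TP
temporal, FC/C central, CP/P parietal, PO/O/I occipital, midline `z`
electrodes following their letter prefix), as the regional membership used
in this kind of analysis is conventionally lobar and is not otherwise
specified. It is overridable per montage. Legacy 10–20 names (T3/T4, T5/T6)
are normalized to T7/T8, P7/P8.

Finite-sample behaviour worth knowing: the estimator `|mean sign|` of a null
pair is positive-biased at level ~ `sqrt(2 / (pi * n_eff))`, where `n_eff`
is roughly twice the band-time product. Narrow bands (delta) therefore show
a higher PLI floor than wide bands (gamma) even for independent signals.
This matches the band-ordering of the levels reported in studies using this
metric and cancels in pre/post comparisons.

## Aperiodic spectral parameters

The aperiodic component of an EEG spectrum follows `P(f) ~ 10^offset /
f^chi`; in log–log coordinates a line with intercept `offset` (log10 power
at 1 Hz, the "y-intercept in the log transformation") and slope `-chi`.
Spectra are estimated per channel and epoch by Welch's method
(`welch_psd()`): 2-s Hamming windows at 50% overlap — seven windows per 8-s
epoch, 0.5 Hz resolution — with one-sided density scaling (the integral of
the density equals the series variance).

`fit_aperiodic()` fits the line robustly with iterative oscillatory-peak
exclusion:

1. ordinary least squares of `log10 P` on `log10 f` over the fit range;
2. residuals from the current line;
3. exclusion of points whose residual exceeds 2.5 robust-scale units (MAD)
   above the line — positive residuals only, i.e. oscillatory peaks;
4. refit; iterate until the excluded set stabilizes (at most 10 passes).

A numerical floor of 1e-6 log10-units on the robust scale keeps noiseless
spectra (residual spread at machine epsilon) from being excluded, so an
exact power law is recovered to machine precision. The one-sided exclusion
rule was chosen over a literal low-quantile threshold because the latter
discards essentially all positive residuals on noisy spectra and biases the
fit low by the mean of the retained half; the MAD rule excludes a 1-log-unit
alpha peak completely while leaving unremarkable noise untouched, and meets
the recovery requirement (median absolute error below 0.1 at 20 epochs)
across the exponent-offset grid.

Open parameters and their defaults:

* **Fit range** 1–40 Hz: above the 0.5 Hz acquisition high-pass shoulder,
  below the mains region; overridable everywhere.
* **Per-epoch fitting.** Parameters are fitted per channel *and epoch* (not
  on session-averaged spectra) because the downstream statistics need
  epoch-level distributions.
* **Offset convention.** Intercept at `log10 f = 0`, i.e. 1 Hz.

Aggregation mirrors PLI: global mean over channels and regional means over
region members, per epoch, separately for offset and exponent.

## Statistics

* **Group comparisons.** For each feature (band x scale x unit for PLI;
  parameter x scale x unit for aperiodic) and each group (responders R,
  non-responders NR), the pre and post distributions are compared by the
  two-sided Mann–Whitney U test. The statistical unit defaults to the
  *epoch*, pooled across a group's subjects (up to 100 values per
  condition). This is the package's reading of the reference analysis — at
  5 subjects per group a subject-level U test cannot produce p < 0.001,
  which the reference results include — and it is the key documented
  ambiguity; `unit_level = "subject"` switches to per-subject medians.
* **FDR families.** Benjamini–Hochberg correction is applied within one
  spatial subdivision at a time: for PLI, all five bands of one subdivision
  (globally; per region; all channels together at the channel scale, with a
  per-region option); for the aperiodic parameters, offset and exponent
  within one subdivision. Significance is `p_fdr < 0.05`; the trend (up or
  down by median difference) is reported only for significant tests.
* **Effect size.** Cohen's d with the pooled-SD formula, reported
  descriptively alongside each test.
* **Clinical outcome.** The Labar index is minus the percentage change in
  monthly seizure frequency, `-100 (post - pre) / pre`; responders are
  subjects with index >= 50. Outcome classes computable from frequency alone
  are bucketed I (>= 80) and II (50–80); finer classes need non-frequency
  clinical information and are out of scope.
* **Outcome correlation.** Per subject and feature, the relative variation
  `(median(post) - median(pre)) / median(pre)` of the epoch-level values is
  correlated with the Labar index by Spearman's rank correlation, at the
  global scale.

The U test, BH adjustment, and Spearman correlation are computed through
base R (`wilcox.test`, `p.adjust`, `cor.test`); the test suite pins them to
independent oracles (full enumeration of rank assignments for small
samples, a brute-force step-up implementation, and hand rank arithmetic).

## The synthetic cohort: what it emulates, what it does not

`generate_epoch_set()` builds each channel as a stationary surrogate with an
exact expected power-law spectrum: amplitude spectrum shaped as the square
root of `10^offset / f^chi` over the synthesis band (0.5 Hz to the Nyquist
or 70 Hz, mirroring the acquisition bandpass), independently randomized
phases, inverse FFT. Band-limited couplings are added per channel pair: a
carrier at the band center whose copy on the second channel is retarded by a
mean lag delta plus von Mises jitter of concentration kappa, redrawn every
0.25 s — so the instantaneous phase difference is von Mises distributed but
slowly varying enough for analytic-signal tracking. Volume conduction is
emulated as a strictly sample-synchronous convex mixture of each channel
with the grand channel mean (leakage 0.2 by default); with no electrode
geometry in the model, the grand mean stands in for "the neighbors", which
also makes the leakage-to-one limit (all channels identical) exact.

The von Mises choice is for tractability: the expected PLI under the model,

    E[PLI] = | P(d in (0, pi)) - P(d in (-pi, 0)) |,  d ~ vonMises(delta, kappa)

is computed by numeric integration (`expected_pli()`) and cross-checked
against direct Monte-Carlo sampling; any symmetric unimodal jitter would
serve, but this one has a closed-form density. Coupling concentrations in
the cohort generator are obtained by numerically inverting this oracle for a
target pair-PLI.

`generate_cohort()` draws seizure diaries (log-normal pre-implant rates;
reduction fractions uniform within [0.5, 1] for responders and below 0.5 for
non-responders, so the Labar index lands on the correct side of the
threshold by construction) and paired pre/post epoch sets. Ground-truth
shifts default to the direction and order of magnitude of the reference
findings: responders' global PLI down in delta and gamma, up in alpha, and
offset/exponent down by 0.1; non-responders' offset/exponent up by 0.2.
Each subject's aperiodic shift keeps its group's sign — the direction is a
group-level ground truth, never flipped for an individual — while its
magnitude scales from 0.5x to 1.5x the group target with the subject's
position inside the group's Labar range (deeper responders drop more,
poorer non-responders rise more). Across the cohort the shift is therefore
negatively monotone in clinical response, the configuration the
outcome-correlation stage is validated against.

Dispersion choices, fixed a priori and deliberately modest: between-subject
SD 0.1 for the offset baseline (0.05 for the exponent), per-channel jitter
0.02, oscillation amplitude three times the background's in-band RMS. Real
cohorts are more dispersed (printed between-subject SDs are ~0.3–0.4); the
generator's purpose is *recoverable ground truth at n = 5 per group*, so a
green end-to-end test establishes that the pipeline detects what was
injected with the right sign and family-wise error control — not that the
clinical effect sizes of a real cohort would reach significance, and not the
reference study's p-values.

The desk-scale validation world is 19 channels (a 10–20 subset with at
least two channels per region), 128 Hz, 20 epochs of 8 s. Epoch count,
epoch length and group sizes are the reference acquisition's; the sampling
rate only changes per-epoch sample counts, not band-time products, so PLI
estimator noise and test power are unaffected while a full 20-replicate
end-to-end validation stays within a desktop CPU budget. The full 61-channel
1,024 Hz world remains the default of `sim_config()`.

Not emulated: biophysical head geometry, non-stationarity, seizure
dynamics, muscle/cardiac artifacts (the reference analysis removes these by
expert epoch selection), and channel-specific aperiodic topography beyond
small jitter.

## Numerical notes and known limitations

* The analytic-signal phase of a jittered carrier is smoothed by the band
  filter, which concentrates the phase-difference distribution slightly:
  the estimated PLI of a coupled pair sits a few percent above the von
  Mises expectation (the generator's own phases match it exactly; the
  bias is an estimator property, bounded and direction-preserving). Tests
  of the generator contract therefore use the generator's true phases,
  while estimator tests pin the exact degenerate cases (constant lag -> 1,
  zero lag -> 0).
* Welch estimation averages log-spectra over ~7 windows; Jensen's
  inequality biases the fitted offset by about -0.03 log10-units. This is
  well inside the 0.1 recovery tolerance and cancels in pre/post
  comparisons.
* Zero-lag mixing attenuates every channel (a convex combination with the
  grand mean has less variance), lowering fitted offsets by a constant
  ~0.18 at leakage 0.2; again common to both sessions.
* EDF I/O quantizes to 16 bits over each channel's physical range; the
  round-trip error bound (half a quantization step) is tested. The internal
  epoch store for exact float round trips is the in-memory `eeg_epochs`
  object; EDF is the interchange format.
* `mad()` of residuals can collapse on pathological spectra consisting
  mostly of one repeated value; the 1e-6 floor and the 5-point minimum
  guard the fit, which otherwise errors out explicitly rather than
  returning a degenerate line.
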
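# vnseeg

Resting-EEG analysis for vagus nerve stimulation (VNS) outcome studies:
phase-lag-index functional connectivity, aperiodic (1/f) spectral
parameters, and the nonparametric statistics that compare them before and
after implantation in responder and non-responder groups.

## The problem

VNS is an implanted neuromodulation therapy for drug-resistant epilepsy.
About half of patients respond (≥ 50 % fewer seizures per month), and there
is no accepted EEG biomarker of response. Two quantities are candidates:

**Phase lag index (PLI).** For two narrowband signals with instantaneous
phases φ_a(t), φ_b(t) (from the analytic signal),

    PLI = | ⟨ sign( wrap(φ_a − φ_b) ) ⟩_t |  ∈ [0, 1],

the absolute mean sign of the wrapped phase difference. PLI is 0 for no
consistently lagged coupling and 1 for a perfectly consistent nonzero lag,
and — because exactly zero-lag differences count as zero — it discounts the
spurious instantaneous coupling produced by volume conduction on the scalp.
Computed per epoch and band (delta 0.5–3, theta 3–8, alpha 8–12, beta
12–30, gamma 30–50 Hz) and aggregated globally, per scalp region, and per
channel.

**Aperiodic spectral parameters.** The non-oscillatory EEG spectrum follows
P(f) ≈ 10^offset / f^χ: in log–log coordinates a line with intercept
`offset` (log10 power at 1 Hz) and slope −χ. Both parameters are fitted per
channel and epoch by robust peak-excluding log–log regression of the Welch
spectrum over 1–40 Hz.

**Statistics.** Pre- vs post-implantation distributions are compared per
group with the Mann–Whitney U test on epoch-level values, Benjamini–
Hochberg FDR-corrected within each spatial subdivision; effect sizes are
pooled-SD Cohen's d. Clinical response is the Labar index,
`−100 (post − pre) / pre` percent change in monthly seizure frequency
(responder ⇔ index ≥ 50), and per-subject relative feature variation is
correlated with it by Spearman's rank correlation.

Because clinical recordings are not redistributable, the package includes a
synthetic-EEG cohort generator (1/f^χ backgrounds with exact expected
spectra, von-Mises phase-coupled oscillations with a closed-form PLI
oracle, zero-lag volume-conduction mixing, seizure diaries) so every stage
is testable against known ground truth. See `vignettes/methods.Rmd` for the
full model description and design choices.

## Worked example

```r
library(vnseeg)

# clinical arithmetic on the ten-patient reference seizure diary
tab <- vns_example_cohort()
lab <- labar_index(tab$pre_rate, tab$post_rate)
classify_responder(lab)$group
#>  [1] "NR" "NR" "R"  "R"  "R"  "R"  "NR" "NR" "NR" "R"

# simulate a 5 + 5 cohort with responder-signed ground truth and analyse it
st <- run_full(run_config(cohort_spec = cohort_spec(seed = 7)))
summary(st)
```

The global-scale comparison table of that run (abridged):

```
   measure  feature group    p_raw    p_fdr trend mean_pre mean_post cohens_d
 aperiodic exponent    NR 8.48e-34 1.70e-33    up   1.9941    2.1633   3.3922
 aperiodic exponent     R 1.61e-27 3.22e-27  down   2.0961    2.0102   2.3709
 aperiodic   offset    NR 1.84e-20 1.84e-20    up   1.3185    1.4886   1.7288
 aperiodic   offset     R 6.99e-08 6.99e-08  down   1.5707    1.5042   0.4577
       pli    alpha     R 1.53e-11 2.55e-11    up   0.1835    0.2232   1.1266
       pli    delta     R 8.56e-13 2.14e-12  down   0.2838    0.2483   1.1676
       pli    gamma     R 1.75e-17 8.76e-17  down   0.1958    0.1491   1.4649
```

The injected ground truth — responders' PLI falling in delta and gamma and
rising in alpha, aperiodic offset and exponent falling in responders and
rising in non-responders — is recovered with the correct trend in every
row, and the correlation stage reports a strong negative Spearman ρ between
the aperiodic parameters' relative variation and the Labar index
(ρ = −0.94 offset, −0.99 exponent in this run), the configuration the
generator injects. (Neighbouring bands sharing a transition region with an
injected band — theta with delta, beta with alpha — pick up attenuated
copies of the same shift; the filters' transition bands genuinely overlap.)

A thin CLI wraps the same pipeline: `inst/cli/vnseeg run --seed 7 --out out/`
writes the cohort, feature, comparison and correlation tables as CSV with a
checksummed manifest; `simulate --edf` exports the synthetic recordings as
16-bit EDF.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the clinical-arithmetic targets
(per-patient Labar indices from the printed pre/post seizure frequencies,
and the responder count under the ≥ 50 % rule applied to the full
ten-patient table) and writes them as a JSON object keyed by target id.
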
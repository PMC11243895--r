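---
title: "Detecting driver fatigue from 2-minute HRV segments: methods and design notes"
author: "hrvfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver fatigue from 2-minute HRV segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Standard short-term heart rate variability (HRV) analysis uses 5-minute
electrocardiogram (ECG) recordings, which is too slow for in-vehicle fatigue
warning. This package implements a complete analysis pipeline for detecting
driver fatigue from **2-minute ECG segments** — the shortest duration the
field's measurement guidelines still consider acceptable — while accounting
for sex differences:

1. cut a 60-minute drive into 59 two-minute windows with 50% overlap;
2. label each window *alert*, *fatigued* or *discordant* from per-minute
   expert ratings (3-of-5 consensus in both minutes, with *fatigued* and
   *very fatigued* pooled); discordant windows are excluded;
3. extract twenty HRV features per window (time-domain, frequency-domain,
   nonlinear);
4. compare alert vs fatigued feature distributions with Mann–Whitney U
   tests, pooled and per sex;
5. classify windows with CART decision trees grown on every 2-, 3- and
   4-feature subset (190, 1140 and 4845 subsets), evaluated on a held-out
   8:2 split with sensitivity, specificity, positive predictive value and
   accuracy (fatigued = positive class).

The cohort that motivated this design is not publicly deposited, so the
package ships a synthetic-data generator that emulates its statistical
structure. Every stage is exercised end to end against that generator.

## The synthetic cohort generator

### RR model

Each subject's RR-interval (tachogram) series follows an interval-domain
model:

$$RR_i = \mu + A_{LF}\sin(2\pi \cdot 0.1\, t_i) + A_{HF}\sin(2\pi \cdot 0.25\, t_i) + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $t_i$ is the cumulative beat time. The two sinusoids place power at
the canonical low-frequency (~0.1 Hz, sympathetic/baroreflex) and
high-frequency (~0.25 Hz, respiratory) bands; a sinusoid of amplitude $A$
contributes band power $A^2/2$ (ms²). Intervals are floored at 300 ms. We
chose direct interval-domain modulation over an integral-pulse-frequency
cardiac model because only the feature-level distributions matter
downstream.

Two numerical details:

* **Harmonic-sampling correction.** Beats sample the tachogram with density
  $\propto 1/RR(t)$, so the beat-averaged mean of a modulated series
  undershoots the programmed offset by roughly
  $(A_{LF}^2/2 + A_{HF}^2/2)/\mu$. The generator adds that correction to the
  offset so that the configured `mean_rr_ms` is the *expected measured*
  mean RR. Per-beat white noise is drawn after the beat arrives and needs no
  correction. With all amplitudes at zero every interval equals
  `mean_rr_ms` exactly.
* **Phase continuity.** A subject's recording is an alert stretch followed
  by a fatigued stretch at a single changepoint; the modulation phase is
  tied to absolute time so the two stretches join coherently.

### Calibration

Per-state, per-sex defaults (`default_state_params()`) are calibrated so
the synthetic groups shift the way fatigued drivers' do: longer mean RR,
larger overall and band-limited variability, a stronger effect in males
than females. Amplitudes are $\sqrt{2P}$ for the target band powers and the
white-noise SD tops the interval SD up to the target SDNN, giving e.g.
sex-independent alert/fatigued means of 801.4/869.9 ms. These defaults are
fixed; they are the study conditions, not tuning knobs.

### Timeline and raters

Fatigue onset is one changepoint per subject, drawn uniformly from
25–50% of the recording (minutes 15–30 at the default 60-minute duration),
so every subject contributes both states with fatigue in the majority. Five
simulated raters then report the per-minute state; each rating is correct
with probability $1-\text{error\_rate}$ (default error rate 0.1, a
plausible level of disagreement for trained raters watching facial video),
a correct *fatigued* rating becomes *very fatigued* with probability 0.3,
and a wrong rating flips the binary state. *Very fatigued* never occurs
during truly alert minutes.

### What the generator does *not* emulate

The noise term is white in the beat domain, whereas real RR noise is
long-range correlated. Consequences worth knowing:

* DFA exponents of synthetic segments sit near the white-noise value
  rather than the ~1.0–1.3 of real drivers, and *increasing* the noise SD
  in fatigue can push correlation-sensitive features (α1, SD2/SD1) in the
  *opposite* direction to real cohorts. The group-comparison machinery is
  validated on the features the generator explicitly encodes (mean RR,
  SDNN, band powers), not on those.
* Segments are far more homogeneous than real physiology, so classifiers
  separate the states almost perfectly (accuracies near 100% on the
  default cohort). Passing tests demonstrate that the pipeline detects the
  encoded effects with the right directions and calibrated error rates —
  not that these accuracies would transfer to real drivers, where the
  motivating study reports 86–95%.
* ECG morphology is a stereotyped Q-R-S-T template: sufficient to exercise
  the 1 kHz ingest and R-peak detection path, not a model of P/T-wave
  physiology, baseline wander or respiration.

## Signal ingest

R peaks are detected with a Pan–Tompkins-style chain: zero-phase 5–15 Hz
Butterworth band-pass, differentiation, squaring, 150 ms moving-window
integration, then adaptive thresholding over the local maxima of the
integrated energy using running signal/noise level estimates
(`level = noise + 0.25 (signal - noise)`, exponential updates) with a
200 ms refractory period. Each detection is refined to the raw-signal
maximum in a window reaching 200 ms back and 100 ms forward, because the
integration stage lags the R wave. Detection is invariant to constant
offset and positive rescaling.

Artifact correction (local-median outlier replacement by cubic spline) is
available but **off by default**: the motivating analysis does not mention
beat correction, and the synthetic data does not need it.

## The twenty features and their conventions

Time domain: MRR (mean RR, ms), DRR (sample SD of RR, ms), MHR (mean of
the instantaneous rates $60000/RR_i$, 1/min — not $60000/\overline{RR}$),
DRMS (RMS of successive differences, ms), NNN15 (count of successive pairs
differing by more than 15 ms), pNN15 (NNN15 divided by the **total number
of intervals**, %, as the feature's definition states — not by the number
of successive pairs).

Frequency domain: the tachogram is resampled at 4 Hz by cubic spline,
linearly detrended, and its PSD estimated by a Hann-windowed averaged
periodogram (64 s windows, 50% overlap) scaled so that total power matches
the signal variance (Parseval-consistent within a few percent on 2-minute
windows). Bands are VLF 0.0033–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz. Short
segments make VLF physiologically unreliable, so VLF enters only the total
power; normalized units are $LF/(LF+HF)\times 100$ and its HF counterpart,
which always sum to 100.

Poincaré: $SD1^2$ is half the population variance of successive
differences, $SD2^2 = 2\,\mathrm{var}_{pop}(RR) - SD1^2$; population (1/n)
variances make the decomposition exact, while DRR deliberately keeps the
sample (n−1) convention of descriptive statistics. SD2/SD1 is undefined
(NA) for a constant segment.

Entropies: ApEn includes self-matches (the classical definition); SampEn
excludes them and counts pairs over the same $N-m$ templates at both
lengths. Both use Chebyshev distance, $m = 2$, and tolerance
$r = 0.2 \times$ segment SD (with a tiny positive floor so constant
segments return 0). Both are validated against quadratic brute-force
oracles to 1e-12.

DFA: integrated mean-centered profile, boxes covered from both ends of the
series, linear detrending per box, $\alpha$ = slope of $\log F(n)$ vs
$\log n$ over 4–16 beats (α1) and 16–64 beats (α2). First-order DFA has a
known small-scale bias: white noise measures ≈0.575 rather than the
asymptotic 0.5 at the α1 box range. α2 requires at least 70 beats and two
boxes at the largest size; otherwise it is NA.

Correlation dimension: Grassberger–Procaccia with embedding $m = 10$,
delay 1, Theiler window 1, Euclidean distances; $D_2$ is the slope of
$\log C(\rho)$ over radii where $0.005 \le C \le 0.5$ (widened when too
few radii qualify). On ~150-beat windows a 10-dimensional embedding is
data-starved; the estimate is still computed — the motivating analysis
reports it — but carries `attr(, "reliable") = FALSE` below 1000 embedded
points.

## Group statistics

Descriptives (mean, sample SD, Q1, median, Q3) use type-7 linear
interpolation for quartiles. The Mann–Whitney U test uses midranks for
ties; for pooled sizes up to 12 the two-sided p-value comes from exact
enumeration of all group labelings, otherwise from the normal
approximation with tie-corrected variance and continuity correction (the
two agree within 0.02 on tie-free 6+6 samples and match `wilcox.test` to
1e-10). The significance level is 0.01 and **no multiple-testing
correction is applied across the twenty features**, matching the
motivating analysis; readers should treat per-feature flags accordingly.

Overlapping windows make segments statistically dependent, and segments
are pooled across subjects without clustering adjustment. The tests are
applied segment-wise anyway — that is the design being replicated — and
this vignette flags the dependence rather than silently changing the
method. The type-I-error calibration test therefore uses non-overlapping
windows, where independence actually holds.

## The CART classifier

The tree is grown from scratch (C++ core): candidate thresholds are
midpoints between consecutive distinct sorted values per feature; the
split minimizing sample-weighted child Gini impurity wins, with
deterministic tie-breaking (feature report order, then lower threshold).
Nodes stop splitting when pure, smaller than `min_samples` (default 5 —
the stopping rule is described only as "a certain threshold", so the value
is configurable and logged), or when no split reduces impurity. There is
no pruning: the replicated procedure describes growth plus stopping only.
Leaves predict their majority class, ties going to *fatigued*, the
majority state. The implementation is validated against exhaustive split
enumeration and against `rpart` training predictions on shared fixtures.

The 8:2 split is segment-level, stratified by label, and shared across all
subsets of one search so accuracies are comparable. Because overlapping
windows share half their data, segment-level splitting leaks information
between train and test; a `subject_wise` split option is provided for
leakage-free evaluation, while the default mirrors the replicated design.
A single split (not repeated splits) is used per search; the search
reports SEN/SPE/PPV/ACC per subset ranked by ACC, ties broken by SEN then
lexicographically.

## Simulation sizes used by the tests

The package's own test suite runs the full default cohort only in the
acceptance script. Statistical property tests use smaller, faster cohorts
chosen once: 4-subject, 12-minute cohorts for test calibration (100 null
replicates, non-overlapping windows) and power (50 shifted replicates),
and 6-subject, 20-minute cohorts for the 50-replicate classifier-power
check, which runs the complete 4845-subset search per replicate. These
sizes keep each property within a few minutes while leaving the binomial
acceptance bands meaningful.

## Worked example

```{r example}
library(hrvfatigue)
report <- run_pipeline(list(seed = 1))
print(report)
head(report$comparisons$all[, c("feature", "med_alert", "med_fatigued",
                                "p", "arrow")])
report$search$male$k4[1, ]
```

## Known limitations

* Synthetic accuracies saturate near 100%; use the margin over the
  majority-class baseline, not the absolute accuracy, when judging the
  classifier stage.
* White beat-domain noise misrepresents correlation-sensitive features
  (α1, α2, D2, SD2/SD1) relative to real cohorts, as discussed above.
* The exact detrending and normalized-unit conventions of commercial HRV
  software are not published; this package fixes and documents its own
  (linear detrend, nu excluding VLF) rather than chasing bit-exactness.
* D2 on 2-minute windows is data-starved by construction and flagged as
  such.
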
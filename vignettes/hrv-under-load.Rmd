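---
title: "Measuring autonomic response to combined cognitive and physical load: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring autonomic response to combined cognitive and physical load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dual-task studies cross a cognitive manipulation (here, the n-back
working-memory task at 1-, 2- and 3-back) with a physical one (isotonic
arm contraction at none/medium/high resistance) and ask how the autonomic
nervous system responds, using heart rate variability (HRV) as the readout
together with subjective workload (NASA-TLX) and behavioral performance.
The expected physiology: rising load raises heart rate, suppresses the
vagally mediated high-frequency (HF, 0.15–0.40 Hz) component of the RR
tachogram, and shifts the LF/HF balance toward the low-frequency (LF,
0.04–0.15 Hz) component.

`hrvload` implements the full measurement chain — ECG to cleaned RR series
to HRV features to group statistics — plus a synthetic-data layer that
makes every stage testable without any subject recordings. Raw subject
data for such studies are rarely deposited, so the package's validation
strategy is *parameter recovery on synthetic data*: the generator plants
known autonomic and behavioral effects, and the pipeline must recover
their directions and magnitudes.

## The synthetic generator

### RR series: integral pulse frequency modulation (IPFM)

The RR generator is an IPFM model, the standard test bench for HRV
spectral estimators. The instantaneous beat rate

$$ m(t) = \frac{1}{\overline{RR}}\Big[1 + a_{LF}\sin(2\pi f_{LF}t+\phi_1)
   + a_{HF}\sin(2\pi f_{HF}t+\phi_2)\Big] $$

is integrated analytically and a beat is emitted at every integer crossing
(the crossing is located by monotone interpolation of the exact integral
on a fine grid, giving sub-millisecond placement). White per-interval
jitter (sd `jitter_sd`) is then added. The virtue of IPFM is that
$a_{LF}$ and $a_{HF}$ map directly onto LF and HF band power, so spectral
estimators can be graded against known ground truth.

Defaults, chosen once as typical resting values for young adults: mean RR
850 ms (~70 bpm), $a_{LF} = a_{HF} = 0.04$ (a few-percent rate
modulation), $f_{LF} = 0.10$ Hz, $f_{HF} = 0.25$ Hz, jitter 20 ms (giving
RMSSD around 30–40 ms). The condition effect map multiplies these per
condition; its defaults encode the directions the dual-task literature
reports — at medium physical load the mean RR multiplier is 0.92 (an 8%
heart-rate increase) and the HF-amplitude multiplier 0.70, with 0.85/0.50
at high load.

What the generator does *not* emulate: respiratory coupling (HF is a pure
tone, not a respiration-driven band), ectopic-beat morphology (cleaning is
exercised with injected interval spikes only), circadian or posture
drifts, and any ECG morphology beyond a three-Gaussian QRS template.
Passing tests therefore show estimator correctness and pipeline
sensitivity under band-structured modulation — not robustness to every
artifact of ambulatory recordings.

### Behavioral and subjective layers

n-back trials are built by first sampling the target positions (beyond the
first `n` letters) and then filling letters so that a position matches the
letter `n` back *iff* it is a flagged target — the target count is exact
by construction, which an exhaustive lag-scan oracle verifies in the
tests. Timing follows the 0.5 s stimulus + 1.5 s interval cadence, 20
letters and 5 targets per trial, 6 trials per run. The printed per-trial
duration (50 s) exceeds the sum of the printed components (2 s
instruction + 40 s stimuli + 6 s break = 48 s); we keep 50 s as the
default per-trial duration — honoring the stated 5-minute run total — and
absorb the 2 s into the inter-trial break. Both are configurable.

Reaction times are lognormal (location–scale), the conventional
right-skewed family for RT data; cognitive level shifts the location (+80,
+160 ms) and the miss probability (+0.07, +0.15), physical level adds
smaller shifts. A hit is a response within the 2-s window from target
onset. TLX ratings are normal draws around condition-shifted dimension
means, clipped to the 21-point scale (stored 0–20; a 1–21 storage flag
exists); the 15 pairwise choices pick the dimension with the larger
underlying demand. The weighted total uses selection-frequency ranks
mapped to weights 1/21 … 6/21, ties receiving the mean of the weights
their rank positions span — which keeps the weights summing to exactly 1,
so equal ratings always reproduce themselves as the total.

Subject random effects (normal, sd 50 ms on baseline mean RR and on RT
location) are shared across a subject's nine conditions, and task order is
counterbalanced by the three-subgroup rotation (1-2-3 / 2-3-1 / 3-1-2)
with subgroup sizes differing by at most one.

## ECG processing

**Denoising** subtracts a running-median baseline (600 ms window — wider
than a QRS-T complex, so complexes are not flattened) and then applies a
20 ms moving average, whose first null at 256 Hz sits near 50 Hz mains.
Edges are handled by reflection.

**QRS detection** is the difference-threshold family: differentiate,
square, integrate over a 120 ms moving window; threshold at 0.4 of a
running peak tracker with a 2 s exponential-decay half-life (primed on the
first 2 s); place each beat at the argmax of the input within the
supra-threshold region; enforce a 250 ms refractory period keeping the
stronger candidate. The threshold is relative, so detection is invariant
to amplitude scaling; a flat-line record returns an empty list with a
warning rather than an error. All parameters are exposed in the pipeline
configuration.

**Outlier screening** follows the fill-outliers rule: an interval is an
outlier if it deviates from the median by more than 3 scaled MADs
(consistency constant 1.4826), plus hard physiological bounds
(250–2000 ms). We use the *global* median/MAD by default and keep the
moving-window (11-beat) variant behind `global = FALSE`: with an 11-beat
window the small-sample MAD is noisy in a scale-invariant way and flags
roughly 3% of perfectly clean Gaussian intervals, and interpolating those
false positives biases RMSSD several percent low. The screen-interpolate
step is iterated to a fixed point (outliers inflate the first-pass scale
estimate, so one pass can leave masked outliers behind); at the fixed
point cleaning is idempotent. Replacement is linear interpolation between
the nearest non-outlier neighbours, with nearest-value extension at the
edges; beat times are not re-synthesized.

## HRV features

Time domain: meanHR is the mean of the instantaneous rate $60000/RR_i$
(the alternative $60000/\overline{RR}$ differs by Jensen's inequality and
is available via `hr_method`); SDNN and SDRT use the sample ($n-1$)
denominator; NN50 counts successive differences *strictly* exceeding
50 ms with pNN50's denominator the number of successive differences.

Frequency domain: the tachogram is mean-detrended, cubic-spline resampled
to an even 4 Hz grid, and fitted with a Burg AR model, order 16 (the
common choice for 5-minute windows; an AIC-selected order is available
behind a flag; Burg is preferred to Yule–Walker for short-window
stability). The one-sided AR density integrates to the resampled series
variance. Band powers are trapezoidal integrals over VLF 0.003–0.040, LF
0.040–0.150, HF 0.150–0.400 Hz; band edges are half-open except the
closed HF upper edge, adjacent bands never double count, and power below
0.003 Hz is excluded from Total. When HF is zero LF/HF is reported as
`NA`, never infinity. The whole 5-minute run is analyzed as one window by
default (per-trial windows would leave under 60 s of data, too short for
the VLF/LF bands).

The cross-check estimator is a Welch periodogram on the same resampled
grid: Hann windows of 60 s at 50% overlap — a resolution of 0.017 Hz,
fine enough to separate the bands, with ~9 averaged segments per 5-minute
window. Two caveats discovered while validating, and how the checks
handle them: (i) the *single-realization* relative deviation between the
AR and Welch band integrals at 300 s has an irreducible tail reaching
~10–15% (periodogram variance, not estimator bias), so the agreement
check asserts the median over five independent series, which sits at
3–5%; (ii) the VLF band carries essentially no generator power, so
relative VLF agreement is noise-on-noise and is excluded from the
comparison.

## The statistics layer

`compare_repeated()` mirrors the assumption-gated analysis convention:
Shapiro–Wilk (α = 0.05) on the within-subject difference scores of every
level pair; all pairs normal → repeated-measures ANOVA omnibus plus
paired t contrasts, otherwise Friedman omnibus plus Wilcoxon signed-rank
contrasts (zeros dropped by the signed-rank convention; exact p below 25
non-zero differences, normal approximation above). Zero-variance
differences are routed to the nonparametric branch, where all-tied data
degenerate to statistic 0 and p = 1. Raw p-values at α = 0.05 are
reported by default; Holm adjustment of the pairwise contrasts is
available behind a flag. The gate's granularity (per feature × factor on
difference scores) is a design choice — finer gating was judged
over-fitted for n = 35.

`correlate_load()` computes Spearman ρ per (HRV feature, load measure)
within each physical-load stratum, pooling the three cognitive levels
within subjects (~3 pairs per subject). The repeated subject
contributions violate independence; this is deliberately reported as a
limitation rather than modeled, matching the analysis convention the
package reproduces. `run_study_analysis()` chains the three stages:
workload/performance manipulation checks, HRV versus physical load within
each cognitive level, and the correlation matrices.

## Validation scale and determinism

Every stochastic check runs under seeds fanned out from one master seed
by `child_seed()` (a string-labelled hash kept below $2^{31}$), so any
subject/condition/replicate stream can be regenerated in isolation. The
shipped checks use: 1000 random series for the time-domain oracle
comparison; 5 × 300-s series for band agreement; 5 levels × 20 replicates
for HF monotonicity; 300-s records for detector fidelity at 10 dB EMG
SNR; and 100 replicates of the n = 35 paired physical-load contrast for
direction-recovery power (observed: ~100% detection of the planted
heart-rate increase and HF-fraction decrease; 5–6% false-positive rate
under an identity effect map). Those sizes give Monte-Carlo error well
below the margins being asserted while keeping the whole suite within a
few minutes on one core.

## Known limitations

- The IPFM + white-jitter model has no respiratory or baroreflex
  coupling; nLF/nHF levels are set by the amplitude ratio and the jitter
  floor, not by physiology.
- Cleaning repairs isolated interval spikes; consecutive-run artifacts
  (e.g., sustained tachyarrhythmia) would be interpolated through.
- The detector assumes a dominant-R morphology of a single polarity; no
  beat-morphology classification is attempted.
- Correlation cells pool repeated measures within subjects
  (~3 per subject); treat the p-values as descriptive.
- ECG I/O is plain CSV with a text header sidecar; binary waveform
  formats are out of scope.
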
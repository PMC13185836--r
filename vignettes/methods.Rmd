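---
title: "Methods: from Go/No-Go psychophysics to population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Go/No-Go psychophysics to population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibropop)
```

vibropop analyzes head-fixed Go/No-Go vibrotactile detection experiments
in which layer-2/3 cortical populations are imaged with a calcium
indicator while a mouse reports stimulus detection by licking. This
vignette documents the models and procedures the package implements, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the numerical choices made where the design was open.

## The task and its behavioral statistics

A session consists of pseudorandomized Go trials (a 500-ms vibrotactile
stimulus followed by a 2-s response window) and No-Go catch trials with
no stimulus. The four outcomes — Hit, Miss, Correct Rejection, False
Alarm — are tallied into rates with the convention that Go trials
canceled by pre-stimulus licking (timeouts) received no stimulus and drop
out of the Go denominator; the timeout fraction itself is reported as the
pre-stimulus lick rate (`outcome_rates()`).

The psychometric function is fit by a binomial GLM with logit link of the
per-trial Hit indicator on stimulus amplitude (`fit_psychometric()`). We
read "detection threshold" as the amplitude at which the fitted curve
crosses P = 0.5, which for a logistic is also its inflection point, and
"accuracy" as the slope of the fitted curve, summarized by its maximum
derivative, slope/4. No lapse or guess parameters are included: the
generator's default lapse is zero precisely so that the generating and
fitting models coincide. Two open choices were resolved as follows:
trials are pooled per mouse across included sessions before fitting
(rather than averaging session-level fits), and timeout-canceled Go
trials are excluded from psychometric denominators because no stimulus
was delivered.

Perfect separation (a step-like rate profile) makes the ML logit fit
diverge; the fallback refits with a small L2 ridge penalty
(`ridge_lambda = 1e-3` on expanded Bernoulli observations) and flags the
fit in its diagnostics. Profiles that are all-zero or all-one, or whose
0.5 crossing falls far outside the tested amplitude range, are flagged
`threshold_defined = FALSE` rather than reported.

Response bias uses the relative criterion
$c' = -\tfrac12\,\frac{z(\mathrm{Hit}) + z(\mathrm{FA})}{z(\mathrm{Hit}) - z(\mathrm{FA})}$
(`criterion_c()`). Rates of exactly 0 or 1 are clipped to $1/(2n)$ and
$1 - 1/(2n)$ before the quantile transform — the standard log-linear
correction; the source convention is silent on this point. Equal clipped
rates leave $c'$ undefined (flagged, never silently NaN).

Trial-by-trial variability is the variance of the Hit indicator per
amplitude, i.e. the Bernoulli variance $p(1-p) \le 0.25$; the normalized
triplet at threshold − 2 µm / threshold / threshold + 2 µm divides by the
Bernoulli maximum 0.25, using the nearest delivered amplitude for each
anchor. Subgrouping of mice uses k-means (k = 2) on the per-mouse
hit-rate profile with 10 restarts under a fixed seed; the cluster with
the lower mean hit rate is labeled hyposensitive-like. Session inclusion
requires a false-alarm rate strictly below 40%; the learning criterion
applies 3-day rolling means (Hit ≥ 80% with FA < 30% for training;
spontaneous licking < 40% for pre-training). An 70% Hit variant of the
criterion is available through the `hit_criterion` argument.

## Fluorescence preprocessing

Traces are neuropil-corrected as $F - 0.7\,F_{neu}$ (coefficient
configurable). The baseline is the mean of the 10-s window with the
lowest standard deviation (stride one frame, ties to the earliest
window), and ΔF/F is $(F_{corr} - F_0)/F_0$; neurons with non-positive
baselines are excluded and logged. Negative corrected fluorescence is
permitted — the correction may undershoot — only the baseline sign
excludes a neuron.

Trials are aligned on the stimulus onset (the scheduled sham onset for
catch trials) with a 1-s pre-stimulus, 0.5-s stimulation and 0.5-s
post-stimulus window: 31 + 15 + 15 frames at 30.96 Hz, with half-open
frame intervals and the onset frame defined as the first frame at or
after the onset time (0-based). z-scores use the mean and SD of the
pooled 1-s pre-stimulus frames across all included trials, per neuron and
per session — we read "across all trials" as pooling, with a per-trial
variant deliberately out of the default path. Pooling across sessions was
considered and rejected: slow drifts in indicator brightness would
contaminate the units.

Frames from the first lick onward are masked invalid, and the tensor API
(`stim_z()`, `trial_mean_stim_z()`) is the only gate through which
stimulus-window statistics read the data, so masked frames cannot leak
into any downstream metric. Trials with fewer than 2 valid stimulation
frames are excluded from stimulus-window statistics (logged); neurons
with zero pre-stimulus SD are flagged constant and excluded.

Savitzky–Golay smoothing (window 10 frames, order 3) is provided for
display only; every analysis runs on raw traces. The even window is
handled by centering at offsets −5…4 and fitting the cubic by least
squares, with edge frames evaluated from the nearest full window's fit.

## The recruitment randomization test

A neuron's per-trial response label compares the 85th percentile of its
z-score over valid stimulation frames against the 95th percentile of a
null distribution: 1,999 time points sampled uniformly without
replacement from the recording, excluding stimulation periods and the
2-s reward windows of rewarded trials. Exceeding the null's 95th
percentile labels the neuron activated (+1) on that trial.

The inhibition comparator is genuinely ambiguous in the field's
formulations: comparing the 10th stimulus percentile against the *95th*
null percentile would label nearly every neuron-trial inhibited. The
default therefore implements the symmetric reading — 10th stimulus
percentile below the 5th null percentile — matching the test's stated
p < 0.05 level; the literal asymmetric comparator remains available via
`literal_inhibition = TRUE`. If both rules fire, the larger percentile
exceedance wins and exact ties yield 0. The null is built once per
neuron per session (per-trial resampling would multiply variance without
changing the level; the sampled-time-points formulation implies a
session-level null). On signal-free standard-normal fixtures the
empirical per-trial false-activation rate of this rule is about 2.5%
(pinned as a regression value in the test suite), with the inhibition
side near 9% — the asymmetry follows from the different percentile
positions (12.9th vs 2.4th order statistic of 15 frames).

Peak amplitude is the extremum of the z-score over valid stimulation
frames (maximum for activated, minimum for inhibited neuron-trials) and
peak delay counts frames from stimulus onset to that extremum. The
detection sensitivity of single neurons uses the equal-weight pooled-SD
form $d' = (\mu_{det} - \mu_{non}) / \sqrt{(\sigma^2_{det} +
\sigma^2_{non})/2}$ on the per-trial mean stimulation-window z-score —
the exact formula is not fixed by convention, and this symmetric form
requires no homoscedasticity assumption beyond averaging.

## Population statistics

Trinary response vectors (one entry per included trial: +1/−1/0) feed
pairwise cosine similarity within cell type; the animal-level score is
the off-diagonal mean. All-zero vectors have no direction and are
excluded from the mean rather than averaged as zeros (which would dilute
coordination estimates toward 0); their count is reported. The E/I ratio
divides activated pyramidal counts by activated interneuron counts per
trial; trials with zero activated interneurons are excluded and counted,
not clamped (an add-one variant exists behind a flag).

Single-cell SNR is the mean over trials of |trial-mean stimulation z −
mean catch activity|; population SNR is the per-trial recruited fraction
divided by the mean catch-trial recruited fraction. The catch-trial
"stimulation window" is a window of identical length placed at the
scheduled sham stimulus time — implied but nowhere stated by the usual
formulation. Condition aggregates are computed per animal first and only
then compared across animals (the animal is the statistical unit); the
per-condition recruitment averages per-trial fractions rather than
pooling trials before dividing. The SNR–recruitment relation across
animals is ordinary least squares with a Pearson correlation test.

## Frame-by-frame decoding

For every imaging frame, an L2-penalized logistic regression classifies
Hit vs Miss from the population's single-frame ΔF/F vector (one scalar
per neuron per trial; a z-scored variant sits behind `feature = "z"`).
Classes are balanced once per session by random undersampling before
fold assignment (the alternative per-fold order is a config away), and a
class with fewer than 4 trials skips decoding for that session — four
outer folds need at least one trial each. The outer loop is stratified
4-fold cross-validation; the inner loop is stratified 3-fold (the
"double cross-validation" formulation does not fix the inner count) and
selects the regularization strength C from {1e-4, 1e-3, 1e-2, 0.1, 1},
with ties broken toward stronger regularization. glmnet's ridge path
implements the per-C fits via λ = 1/(nC), unstandardized, matching the
scikit-learn parameterization. Test-fold predictions are pooled into
per-frame rates: overall accuracy, Hit accuracy P(pred Hit | Hit) and
Miss error P(pred Hit | Miss) — the two curves of the conventional
display. Fold-averaged rates were considered for the Miss-error curve;
pooled predictions are the default because they weight folds by size.

Every frame also trains a second model on label-shuffled training data
with identical folds and undersampling — the chance-level baseline.
Zero-variance feature columns are dropped within each training split; if
none remain the model falls back to the training majority (accuracy 0.5
in expectation on balanced data). Window summaries average per-frame
accuracies over the stimulation window (0–500 ms, 15 frames at 30.96 Hz)
or the pre-stimulus window (−200–0 ms, 6 frames).

## The synthetic cohort generator

The generator produces seeded sessions with the statistical structure
the analysis assumes — it is the package's test bed, not a biophysical
model. Trial sequences follow the task protocol (300 pseudorandomized
trials; 75%:25% Go:No-Go at 15 µm/40 Hz in training, 90%:10% over
amplitudes {2,…,12} µm at 10 Hz in testing; amplitude counts balanced
within ±1; ITIs uniform in 5–10 s). Outcomes are Bernoulli draws from a
logistic psychometric with optional lapse (default 0) and a fixed
false-alarm rate. First-lick times are drawn uniformly between 150 ms
after onset and the end of the response window: this deliberately places
a share of first licks inside the stimulation window so that the
first-lick masking machinery is exercised end to end — a generator that
confined licks to the post-stimulus response window would leave the mask
vacuously true.

Traces are built per neuron in ΔF/F units as evoked calcium transients
(instantaneous rise, single-exponential decay, τ = 0.2 s — a fast
indicator regime) plus a small loading on a slow common signal (white
noise low-passed at ~1 Hz) plus white Gaussian noise (SD 0.06), then
scaled around a baseline fluorescence of ~100 a.u. The neuropil channel
shares the common signal and is mixed into the measured ROI trace as
`F = F_true + 0.7 * Fneu`, so that the standard correction removes the
contaminant in expectation.

Recruitment is drawn per trial and neuron from
`recruit_floor + recruit_amp_gain * amp/12 + recruit_detect_boost *
detected` (defaults 0.05/0.15/0.15), scaled by `recruit_scale`;
catch trials recruit at the floor alone, and deliberately ignore
`recruit_scale` — the hyposensitive preset models a deficit of
stimulus-evoked recruitment while spontaneous dynamics stay intact,
which is also what keeps its population SNR (stimulus over catch
recruitment) genuinely lower. A per-trial shared excitability
multiplies every neuron's recruitment probability by
`1 + loading * e_t` with `e_t ~ N(0,1)`: this co-modulation is what the
`shared_gain_loading` parameter (default 0.6) actually controls, and it
sets the pairwise cosine similarity of the trinary vectors. An additive
common trace alone cannot play this role — after z-scoring, its
amplitude is normalized away (the pre-stimulus SD scales with the
loading itself), so only co-recruitment survives as ensemble
correlation. About 15% of neurons respond with negative-going
transients.

The hyposensitive-like preset (`hypo_mouse()`) shifts the threshold by
+4 µm, scales recruitment probability and evoked gain by 0.6, adds 60 ms
of latency, and halves the shared-gain loading — chosen to reproduce the
directional contrasts of a hyposensitive phenotype, not any particular
magnitudes. No published quantitative generative model of such data
exists; all generator magnitudes are presets.

What the generator does not emulate: spike-to-calcium biophysics, motion
artifacts, imaging-frame rendering, neuron-specific tuning beyond
amplitude scaling, slow representational drift, and temporally
structured (autocorrelated) noise beyond the 1-Hz common signal. Passing
tests therefore demonstrate that the pipeline's statistics behave
correctly under the assumed structure — they do not certify performance
on real recordings with richer noise.

## Numerical choices and problem sizes

All percentiles use R's default type-7 (linear interpolation) quantiles,
matching the common array-library convention. Baseline ties resolve to
the earliest window after rounding the running variance to 12 significant
digits to suppress floating-point jitter. All randomness flows through
explicitly passed seeds; child seeds are derived per stage and per mouse,
so cohorts are reproducible and mice independent.

The test suite runs the heavier calibration studies at deliberately
scaled sizes chosen to keep a full run comfortable on a laptop while
leaving Monte-Carlo error well inside the asserted tolerances: the
chance-level calibration uses one 240-trial, 60-neuron session; the
group-contrast study uses 10 replicates of 5 mice per group with
90-trial, 40-neuron sessions, decoding every third stimulation-window
frame; the pre-stimulus null check uses 10 simulated mice. The
acceptance script reports the shuffled-label stimulation-window accuracy
of a 240-trial, 60-neuron session.

## Known limitations

The percentile test's false-positive rate rises when within-window
activity is temporally correlated (fewer effective samples than frames);
on generator output with the default common signal the catch-trial
"recruited" fraction is therefore above the iid-noise level, as it would
be on real data. The ridge fallback for separated psychometric fits
shrinks the slope and so biases the threshold slightly toward the center
of the amplitude range. Decoding with ~10 trials per class is noisy;
results for sessions near the 4-trial minimum should be read as
qualitative. The CLI covers the simulate/analyze/report flow for
simulated cohorts; applying the pipeline to real recordings means
providing `trials.csv` and the trace container in the documented schema.
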
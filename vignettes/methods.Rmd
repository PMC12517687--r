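---
title: "Methods: behavioral and neuronal discriminability for Go/No-Go auditory tasks"
author: "neurodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and neuronal discriminability for Go/No-Go auditory tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodisc)
```

## Scope and data model

`neurodisc` analyses Go/No-Go auditory discrimination sessions in mice: a
lick-trained animal hears pure tones around a 10 kHz category boundary and
is rewarded for licking after Go tones and for withholding after No-Go
tones. The learned stimuli come in two difficulties — an *easy* pair one
octave apart (7.07 vs 14.14 kHz) and a *hard* pair a quarter octave apart
(9.17 vs 10.91 kHz, the exact `10 * 2^(±1/8)` kHz pair around the
boundary) — plus low-probability unreinforced *probe* tones spanning the
learned range. Alongside behavior, the package analyses spike trains of
sorted units recorded in auditory cortex during the task and during passive
pure-tone listening.

A session is a plain-text directory (`trials.tsv`, `licks.tsv`,
`spikes.tsv`, `units.tsv`, `meta.json`), all times in seconds with tone
onset defining time zero for every trial-aligned quantity. Every analysis
window in the package is half-open, `[start, end)`, so no spike or lick is
ever counted twice at a bin edge.

## Behavioral model

Outcomes are classified from the lick stream: a go trial with at least
`lick_threshold` licks inside the 2 s response window is a hit (else miss);
a no-go trial likewise a false alarm (else correct reject). The threshold
is 1 lick for the head-fixed protocol and 5 for the automated home-cage
protocol; the window is anchored at tone offset by default. Sensitivity
and bias use the equal-variance Gaussian signal-detection forms

$$d' = \Phi^{-1}(H) - \Phi^{-1}(F), \qquad
  c = -\tfrac{1}{2}\left(\Phi^{-1}(H) + \Phi^{-1}(F)\right),$$

with rates clipped to $[0.01, 0.99]$ before the probit. Only the upper
clip is strictly needed to keep perfect hit rates finite; we clip
symmetrically so that $d'$ stays finite *and* antisymmetric under
label exchange, which the tests exploit. Endpoint $d'$ defaults to the
last 100 trials per task; the running $d'$ uses 25-trial bins.

Psychometric curves are unity-normalized lick rates fitted with
$S(t) = a / (1 + e^{-(t-b)/c})$ over $t = \log_2(\mathrm{freq}/1\,\mathrm{kHz})$.
The response direction is auto-detected by rank correlation and falling
curves are fitted on the mirrored axis; initialization is a fixed rule
(a = max rate, b = abscissa nearest half-max, c = span/10), so the fit is
deterministic. Degenerate inputs (flat rates) are returned flagged, never
silently replaced.

## Single-unit selection and firing properties

A unit is *auditory responsive (excited)* if its per-trial evoked rate
(tone onset to 50 ms after offset) exceeds its baseline rate by a
right-sided Wilcoxon signed-rank test at $\alpha = 0.05$. Two baseline
definitions coexist deliberately, each serving its own quantity: the test
baseline is $[-200, -50)$ ms before onset (a guard gap against
anticipatory activity); the spontaneous rate reported in the firing
properties uses the full $[-200, 0)$ ms.
Zero differences are excluded (standard signed-rank practice) and the test
switches from the exact to the normal approximation at $n = 25$ paired
differences, or whenever ties are present.

PSTHs are 1 ms histograms smoothed with a unit-mass Gaussian kernel
(sd 5 ms), which preserves total spike mass to within edge effects.
Firing properties include the fraction of trials whose evoked count
strictly exceeds the baseline count (strict inequality, no margin), the
median-across-trials first-spike latency (the median is robust to
outlier trials), the
FWHM of the smoothed PSTH measured above the spontaneous-rate floor, and
lifetime sparseness over the learned tones,

$$S = \frac{1 - (\sum r_i / n)^2 / (\sum r_i^2 / n)}{1 - 1/n},$$

which is 0 for a uniform response, 1 for a one-hot response, and invariant
to rate rescaling.

## Time-resolved ROC discriminability

Discriminability between two trial classes (e.g. hits vs false alarms) is
the Mann–Whitney AUC of per-trial spike counts, with ties credited 0.5;
values above 0.5 mean the second class fires more. The trace uses 50 ms
windows advanced in 25 ms steps — a 25 ms-resolution running window —
timestamped at the window center. Per window, 20 trials per class are
drawn without replacement and the AUC averaged over 100 such draws. The
trace is then baseline-adjusted, `(AUC − mean pre-onset AUC) + 0.5`,
using windows fully inside $[-200, 0)$ ms, and clipped to $[0, 1]$; the
baseline span and the clipping are package choices, made symmetric so the
null stays centered and the invariants stay testable.

The shuffle null repeats the identical pipeline with class labels permuted
over the union of the two sampled sets on each iteration, including the
baseline adjustment, and summarizes per-bin mean and SD over iterations.
Each shuffled iteration is a single resample (not a mean of 100), which
makes the null band conservative. Significance is one-sided — adjusted
AUC above `null mean + 3 SD` — because baseline adjustment centers the
null at 0.5 and every contrast is directional; per-bin (not trace-wide)
null SDs are used. Onset latency is the first significant window center at
$t \ge 0$, duration is `step × (number of significant bins)` (possibly
non-contiguous), and the maximum is taken over post-onset bins.

Contrasts: stimulus discriminability is hits vs false alarms within a task;
choice discriminability is false alarms vs correct rejects per task with
metrics averaged across tasks (same No-Go stimulus, different behavior);
the novice-mode contrast is go vs no-go per task. Miss and probe trials
never enter any contrast.

## Population decoding

Hit and correct-reject trials of one task form a trials × units count
matrix over the first 200 ms after onset; sessions with fewer than 20
responsive units or fewer than 20 trials in either class are rejected with
a reason code (thresholds inclusive). The decoder is a shared-covariance
Gaussian linear discriminant with the pooled covariance shrunk toward
scaled identity by the Ledoit–Wolf analytic rule — shrinkage keeps the
decoder stable at 20–40 trials × ≥ 20 units without ever needing a
singularity fallback. Accuracy is the mean over 100 random splits holding
out 10 trials per class (the repeat count is a free parameter; 100 keeps
the split noise well below the reported precision). Equal class priors
are used.

The time-resolved decoder fits an independent LDA per 50 ms bin. Decoding
latency uses a 100 Hz trace (50 ms windows advanced in 10 ms steps — the
stated sampling frequency fixes the step, not the window placement,
which we timestamp at the window center): the baseline mean and SD are
taken over windows fully inside $[-500, -50)$ ms and latency is the first
post-onset time above `baseline mean + 3 SD` within the first 200 ms;
sessions that never cross are excluded from latency summaries.

Fisher separation is the closed-form maximizer of the between- over
within-class variance ratio,
$S = \Delta\mu^\top (\Sigma_1 + \Sigma_2 + \varepsilon I)^{-1} \Delta\mu$,
with $\varepsilon = 10^{-6} \times$ the mean diagonal of
$\Sigma_1 + \Sigma_2$ — a scale-free ridge that handles rank deficiency
while preserving affine invariance to first order. Single-trial variance
z-scores each unit across all trials of the session, then averages the
per-unit within-class variances with equal unit weight. The hard-vs-easy
separation relationship is fitted as $S_{hard} = \beta S_{easy}$ with
Huber loss and no intercept (`MASS::rlm`).

## Passive-listening tuning

The frequency-response area is the mean rate per (frequency × level) cell
over tone onset to 50 ms after offset. All tuning metrics are evaluated at
62 dB SPL, the level closest to the 72 dB task level that avoids ceiling
effects. Per-frequency significance uses the same one-sided signed-rank
test as unit selection; the best frequency is the significant frequency
with maximal rate. Bandwidth counts the largest contiguous significant run
containing the best frequency ("adjacent" is read as contiguous; isolated
significant cells are ignored), subtracts the expected number of false
positives ($\alpha \times n_{freqs} = 1$ for 20 tones at 0.05 — the
natural correction for 20 independent tests; the
subtraction may be fractional and is floored at zero), and multiplies by
the 0.1661-octave step. Population sparseness is the fraction of
significant unit × frequency responses.

The pairwise neural d′ between frequencies $p$ and $q$ is a
signal-to-noise ratio on per-trial rates, defined here in the form that is
dimensionally consistent for scalar single-neuron responses: numerator
$|\mu_p - \mu_q|$, denominator the mean over all cross-trial pairs of
$|\hat p_i - \hat q_j|$. This makes the matrix symmetric with zero
diagonal and invariant to rate rescaling; identical trial sets give 0 by
convention with a warning. The summary value averages pairs inside the
learned spectrum (7.07–14.14 kHz).

## The synthetic-session generator

The generator exists so every stage has a recoverable ground truth; its
defaults are the experimental protocol conditions, not tuning knobs. Behavior follows the
SDT model with the convention $P(\mathrm{lick}\,|\,\mathrm{go}) =
\Phi(d/2 - c)$ and $P(\mathrm{lick}\,|\,\mathrm{nogo}) = \Phi(-d/2 - c)$,
so the planted $(d, c)$ are exactly what the estimators measure. Defaults:
100 ms tones, 2 s response window anchored at offset, 6–8 s inter-trial
intervals, no-go probability 0.45, probe probability 0.10 (five probe
tones at 2% each). Probe lick probabilities follow a sigmoid in octave
distance from the boundary scaled by `d_easy` — a simulator choice, since
only the go/no-go probabilities are pinned by the model. Responding trials
receive lick trains that always reach the lick threshold, and outcomes are
assigned by running the package's own classifier on the generated licks,
so generator and classifier cannot disagree.

Spiking is an inhomogeneous Poisson process per unit: a homogeneous
baseline, a tuned evoked transient (Gaussian tuning in log2 frequency,
peak 1; alpha kernel $(t/\tau)e^{1-t/\tau}$ shifted by the evoked
latency; gain monotone in sound level), and a choice step on lick trials.
Evoked and choice components are drawn by thinning with the analytic rate
maximum as ceiling, and superposition of independent Poisson processes
gives the exact summed-rate process. Per-trial multiplicative gain noise
(gamma, mean 1, CV 0.3 by default) is applied to the evoked term only, so
the planted choice step stays exactly `choice_gain` — this keeps
choice-onset recovery a test of the analysis rather than of the noise
model. Trial-to-trial noise is independent across units; noise
correlations in real recordings are not modeled, so independence is a
documented modeling choice, and passing recovery tests therefore says
nothing about correlated-noise regimes in real data. Other real-data features the
generator does not emulate: non-Poisson spiking statistics (refractoriness,
bursting), slow drift in excitability, motivational state changes across a
session, and heterogeneous per-unit latencies.

The hard tone pair deserves a note: the quarter-octave pair around 10 kHz
is exactly 9170.0 and 10905.1 Hz, and the generator and the `"strict"`
protocol validator use these values (a pair quoted as 9.17/10.95 kHz
would be 0.256 octaves apart, not 0.25; 10.905 kHz is the exact value). The
passive protocol uses 20 tones from 4 kHz in 0.1661-octave steps
($\log_2 10 / 20$), five levels (32–72 dB), 16 repetitions per cell, 1 s
between onsets.

## Numerical choices, tie-breaks, degenerate inputs

* AUC ties are credited 0.5 via midranks; with the full class sampled and
  one iteration, the resampled AUC reduces exactly to the Mann–Whitney
  statistic.
* Shuffled traces of constant counts collapse to SD 0 and mean 0.5;
  significance is then never declared (threshold is strict `>`).
* `fisher_separation` of identical class means is exactly 0; the ridge is
  skipped conceptually (it only shifts eigenvalues by
  $10^{-6}\,\bar\sigma^2$).
* Zero-variance units are excluded from single-trial variance with a
  warning; if none remain the operation errors.
* Psychometric fits with flat rates are flagged `degenerate`; fewer than 4
  distinct frequencies is an error.
* Running-d′ bins missing a trial category give `NA`, never a clipped
  pseudo-rate.
* All seeded operations save and restore the caller's RNG state, and the
  pipeline derives per-stage, per-session sub-seeds from one master seed by
  a fixed multiplicative scheme, so stages are reproducible in isolation.

## Problem sizes used in the tests

The test-suite and demo sizes were chosen as the smallest that keep every
recovery property comfortably inside its statistical tolerance: behavioral
grids at 2000 trials per cell (binomial SE on $d'$ ≈ 0.1–0.2), onset
recovery with 20 units per planted onset, decoding calibration over 50
permuted-label seeds, latency recovery over 10 sessions of 20 units, and
pipeline demos with 22-unit, 260–320-trial sessions. The cohort demo in
`analysis/` uses two sessions per cohort, which is ample for its
qualitative orderings but deliberately not a power analysis.

## Known limitations

* The resampled AUC with 20-trial draws is biased toward 0.5 relative to
  the full-sample AUC when classes are imbalanced and large; the
  acceptance tests bound this at ±0.02 for 40-trial classes.
* The window-center timestamp convention biases detected onsets up to half
  a window early for very strong signals (bounded by the recovery
  tolerances in the tests).
* Where a convention had to be fixed (pairwise-d′ denominator,
  bandwidth false-positive correction, duration of non-contiguous
  significance), the choice is documented above; alternatives would change
  absolute values but not the monotonicity properties the tests check.
* No inferential statistics across cohorts are provided (the relevant
  tests are off-the-shelf); region labels are carried as grouping columns
  only.
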
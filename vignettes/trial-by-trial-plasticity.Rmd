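---
title: "Trial-by-trial climbing-fiber plasticity and VOR gain analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-by-trial climbing-fiber plasticity and VOR gain analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cerebellar climbing fibers (CFs) are thought to carry the error signals that
teach the cerebellum. Each CF spike evokes exactly one complex spike (CS) in
its target Purkinje cell, so an extracellular Purkinje recording gives
simultaneous access to the putative teaching signal (CSs, about 1 sp/s) and
the cell's output (simple spikes, SS, tens of sp/s). During motor learning in
the vestibulo-ocular reflex (VOR), retinal slip — image motion left over when
eye movements fail to compensate head movements — drives CF firing. Whether
that CF activity actually induces the plasticity underlying learning can be
probed trial by trial: because a CF fires probabilistically, trials with and
without a CS can be compared within the same training session. If CF spikes
trigger plasticity, the SS response on the trial *after* a CS trial should be
depressed relative to the trial after a no-CS trial.

`vortrial` implements that analysis end to end, together with the mouse
behavioural analysis of VOR gain learning and a synthetic session generator
with implantable, known plasticity so that every stage of the pipeline can be
verified by parameter recovery. No recorded data ship with the package; all
tests and the acceptance script run on synthetic sessions whose ground truth
is known by construction.

# The trial-by-trial statistic

For each cell and condition:

1. SS firing rate is estimated by the reciprocal-interval method: at any time
   in the half-open interval $(t_i, t_{i+1}]$ between consecutive spikes the
   rate is $1/(t_{i+1}-t_i)$. The half-open convention avoids assigning two
   rates at a spike time, and makes the time integral of the rate over the
   span of the train telescope exactly to $N-1$ spikes.
2. Saccades are detected on eye velocity by a velocity threshold on the
   residual from the stimulus-predicted component, excised, and — when
   shorter than `max_gap` (default 200 ms) — linearly interpolated; the SS
   rate receives the identical treatment (interpolated where eye velocity was
   interpolated, gap-marked where it was removed). Gaps propagate as `NA`
   through every downstream average.
3. A 10 s centred moving-average baseline is subtracted from the rate to
   remove slow drift. Whether such a baseline should trail or be centred is a
   free choice; centred is used because it is phase-neutral with respect to
   the implanted trial-to-trial changes.
4. Trials in the CF's 'on' direction are selected (ipsiversive stimuli for
   VOR-increase training, contraversive for VOR-decrease). Opposite-direction
   trials, on which CFs rarely fire, are excluded and do not break pair
   adjacency.
5. A trial is a *CF trial* if at least one CS falls in the window
   75–250 ms after stimulus onset (half-open, closed on the left).
6. All sliding pairs of consecutive same-direction trials are classified as
   CF–NoCF, NoCF–NoCF, NoCF–CF or CF–CF; pairs containing an invalid trial
   (more than 50% gap samples in the analysis span, configurable) are
   dropped, and pairs never span a block boundary when a block label is
   present.
7. For each pair, the second trial's baseline-subtracted rate minus the
   first's is taken sample-wise over the first 100 ms of the trial, pair
   differences are averaged per cell, smoothed with a 25 ms boxcar, and cells
   are averaged with equal weight into a grand average. The 100 ms cap
   exists because CF responses to the stimulus begin at roughly that latency,
   so the CS-triggered pause in simple spiking cannot contaminate the span.
   Smoothing is linear, so applying it before or after averaging differs only
   at the span edges; it is applied after averaging, inside the span.

## The bootstrap null

Significance is assessed against a matched-count bootstrap: per repetition
and per cell, as many pairs as were observed in the target class are drawn
with replacement from that cell's pool of *all* consecutive-trial pairs (all
four classes, same condition), per-cell means are averaged across cells, and
the band is the pointwise mean ± 2 SD over 1000 repetitions. Samples where
the observed grand trace leaves the band are flagged. Two choices here were
genuinely open and are recorded as package policy:

* sampling is with replacement (switchable via `replace = FALSE`);
* pools are per condition — pairs from different training conditions are
  never mixed, since the conditions are analysed separately throughout.

The band is pointwise, not simultaneous, matching the ±2 SD construction.

## Session slopes

The gradual within-session change is measured by ordinary least squares on
the per-trial response (mean baseline-subtracted rate over the first 100 ms)
against trial number, giving sp/s per trial, and slopes from all sessions of
a condition are tested against zero with a one-sample t test.

# The synthetic session generator

The generator emulates the primate pulse paradigm: trapezoidal head-velocity
pulses (15 °/s plateau, 25 ms linear acceleration; durations drawn from
{250, 500, 1000} ms) in alternating directions with same-direction onsets
spaced exactly 2.192 s; traces at 500 Hz. Simple spikes are an inhomogeneous
gamma-renewal process (shape 4 by default, matching the regularity of
Purkinje trains; a pure Poisson model would make the post-CS pause ill
defined) generated by time rescaling, with baseline 71 sp/s and a
stimulus-locked modulation (default +30 sp/s in the 'on' direction, scaled
by the head-velocity profile). On each 'on'-direction trial a CS occurs with
probability `cs_prob_in_window`; background CSs occur at 0.5 sp/s elsewhere
but are thinned out of all trial windows so the realized flags equal the
ground truth exactly. Every CS silences simple spikes for `pause_duration`
(default 15 ms). Eye velocity is `-vor_gain` times head velocity plus
Poisson-timed 30 ms saccade pulses (~100 °/s) and white noise; the visual
stimulus moves opposite to the head for increase training and with it for
decrease training. All randomness in a session flows from one seed.

## CS latency

Within-trial CS latency needs a distributional assumption. Latencies are
drawn uniformly — the least-informative choice on an interval — but on
[100, 250) ms rather than the full detection window, because stimulus-driven
CF responses begin at about 100 ms; that latency is also the reason the
analysis span stops at 100 ms. Keeping simulated latencies at or beyond
100 ms means the CS-triggered pause cannot overlap the analysed span, which
mirrors the logic of the span cap itself. The range is configurable
(`cs_latency_range`).

## The plasticity implant and why its persistence defaults to 1

A CS on 'on'-direction trial $k$ adds `plasticity_delta` (sp/s) to the rate
during the response window of trial $k+1$ of the same direction, retained at
a fraction $s$ = `plasticity_persistence` per subsequent trial, so trial
$k+j$ receives $\delta\,s^{j-1}$.

The choice of the default $s$ matters more than it may appear. Write
$o_k$ for the accumulated offset on trial $k$ and $X_k$ for the CS
indicator. For any $s<1$ the offset process is stationary, and the class
expectations of the consecutive-trial difference $o_{k+1}-o_k$ are

$$\mathbb{E}[\Delta \mid \mathrm{CF\text{-}NoCF}] = \delta(1-p), \qquad
  \mathbb{E}[\Delta \mid \mathrm{NoCF\text{-}NoCF}] = -\delta p,$$

independent of $s$ ($p$ = CS probability per trial): the first trial of a
pair may itself sit one trial after an earlier CS, which attenuates the
CF–NoCF readout and leaks an opposite-signed bias into the NoCF–NoCF class.
(The stationarity constraint makes this unavoidable — the class means,
weighted by class probabilities, must sum to zero.) Only in the accumulating
regime $s = 1$ does the pair difference reduce to
$\Delta = \delta\,X_k$ exactly: CF–NoCF recovers $\delta$ without
attenuation and NoCF–NoCF is exactly centred on zero. Since the generator's
purpose is verification by parameter recovery, the default is $s=1$;
smaller values are available to emulate the rapid decay of single-trial
changes that physiology suggests, with the attenuation above describing
exactly what the statistic will then report.

## CS probability default

The default `cs_prob_in_window = 0.05` reflects the sparse-firing regime of
CFs (an individual CF does not fire on every trial even when the error is
present) and a positivity constraint of the accumulating implant: the
accumulated depression after $n$ CS trials is $|\delta| n$, and with
$p=0.05$, 200-trial sessions and $\delta = -8$ sp/s the expected
accumulated offset (~80 sp/s) stays within the firing range of a 71 sp/s
cell with a +30 sp/s stimulus modulation. In the upper tail of the CS count
the rate can still reach its floor of 0 late in a long session; rates are
clamped at zero there, which attenuates recovery slightly (well under
1 sp/s in expectation at the default settings). Both the probability and the
delta are configurable per study.

## Mouse sessions

The mouse generator produces 1 Hz, ±10 °/s sinusoidal head velocity at
1000 Hz; smooth eye velocity is $-g$ times head velocity shifted by the
ground-truth phase, plus saccades and noise, and eye *position* is the
running integral. Head position is integrated through the same numerical
path, for the reason given below.

# VOR gain analysis

Eye and head position are low-pass filtered (third-order Butterworth, 9 Hz
cutoff) forward and backward — zero phase, so latencies used elsewhere are
not shifted — and differentiated by central differences. Saccades are
removed from the eye velocity by a velocity threshold on the residual from a
sine fit (default threshold 3 robust SDs, overridable), and the same epochs
are dropped from the head velocity so that both sine fits see identical
samples: filtering, differentiation and sample selection are then a common
linear operation on both channels and cancel exactly in the gain ratio.
Gap samples are dropped from the fit rather than interpolated — least
squares handles missing samples natively.

The sine fit is linear in parameters at the known stimulus frequency
($a\sin + b\cos + c$), hence closed form; amplitude $\sqrt{a^2+b^2}$, phase
$\operatorname{atan2}(b,a)$ in (−180°, 180°]. Gain is the eye/head
amplitude ratio; the eye–head phase difference is reported separately
(compensatory eye velocity is anti-phase, so the gain itself uses
amplitudes only). When several test blocks are available, gain is computed
per block and averaged, keeping blocks statistically independent. Learning
is the percent change in gain from the pre-training baseline.

Group comparisons follow a normality gate: every group is screened with the
Shapiro–Wilk test at α = 0.05; if all groups pass, the parametric test is
used (one-sample t, unpaired t, one-way ANOVA with Dunnett's post-hoc, or
repeated-measures ANOVA with Fisher-LSD-style post-hocs), otherwise the
non-parametric counterpart (Wilcoxon signed rank, Mann–Whitney,
Kruskal–Wallis with Dunn's post-hoc, or Friedman). Constant data carry no
evidence against normality and are treated as degenerate (p = 1 for
identical groups rather than an error).

# Numerical choices

* **Conventions.** Times in seconds (float64), angles in degrees, rates in
  sp/s; all intervals half-open [start, end); trial-relative time 0 is
  stimulus onset; contraversive motion is positive.
* **Zero-phase filtering.** The forward–backward Butterworth pass is
  preceded by mean-centring and odd-reflection padding of six filter time
  constants at each end, so start-up transients decay inside the pad; both
  operations are linear, preserving the exact proportionality that the gain
  ratio relies on.
* **Boxcar windows.** All moving averages (baseline, smoothing) use a
  symmetric centred window (2⌊w/2⌋+1 samples), shrink at the edges, and
  exclude gap samples from each window mean.
* **Histogram binning.** CS counts are binned with a 10⁻⁹ s tolerance on
  the bin edge so that spikes computed at an exact edge land in the
  half-open bin they belong to.
* **Degenerate inputs.** Fewer than two spikes yield an all-gap rate trace;
  zero pairs in a class yield an empty result with a warning; a bootstrap
  with `n_reps = 0` skips the band with a warning; zero-variance slope sets
  report a degenerate flag with p = 1 against a null of zero.
* **Determinism.** Sessions are bit-reproducible from (config, seed); the
  RNG state of the caller is saved and restored around generation.

# What the synthetic tests do and do not show

The generator reproduces the features the analysis is sensitive to — fixed
trial timing, probabilistic in-window CSs, post-CS pauses, renewal-regular
SS trains, rate drift (via the implant), saccades, measurement noise — but
not everything real recordings contain: no unit isolation errors, no
stimulus-locked CS latency structure beyond the uniform assumption, no
visually driven eye-movement components in the first 100 ms, no torsional or
vertical eye movements, no biophysical Purkinje dynamics, and no learning
inside the generator beyond the implanted offsets. Passing parameter
recovery therefore validates the *analysis chain* — that the statistics
measure what they claim with correct calibration — not any biological claim
about real cells.

Problem sizes used by the verification suite were chosen to make the checks
sharp at desk scale: recovery of an implanted −8 sp/s change uses 40 cells ×
200 trials with 1000 bootstrap repetitions; null-band calibration uses 200
simulated datasets of 6 cells × 60 trials at 200 repetitions; classifier
equivalence uses 1000 random trial tables against a brute-force double loop;
test calibration uses 10⁴ simulations.

# Known limitations

* The saccade detector is a single velocity-threshold rule used for both
  species; the threshold default (3 robust SDs) is a heuristic and should be
  reviewed against real traces.
* The spikelet detector (relative-prominence local maxima within 6 ms of
  the initial transient) replaces a manual count; its two thresholds are
  configurable but not validated against annotated waveforms.
* Bootstrap pools mix pair classes within a condition but never across
  conditions; if cells contribute very different pair counts the matched
  draw preserves each cell's count but not any within-session ordering.
* The accumulating implant approaches the firing-rate floor in long,
  high-CS-rate sessions (see above); recovery studies beyond a few hundred
  trials should lower the CS probability or the implant magnitude.
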
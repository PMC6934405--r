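---
title: "Simulating amplitude-modulation training and tone-vocoded speech perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating amplitude-modulation training and tone-vocoded speech perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocotrain)
```

## The scientific setting

Cochlear-implant processors discard the temporal fine structure of speech and
deliver mainly the slow amplitude envelope of a handful of frequency bands.
A tone vocoder is the standard acoustic simulation of that listening
situation for normal-hearing participants: the signal is split into a few
contiguous analysis bands, each band's envelope is extracted and re-imposed
on a sine carrier at the band's center frequency, and the carriers are
summed. Perceiving vocoded speech therefore depends almost entirely on
temporal-envelope (TE) sensitivity, which raises a natural training
question: does practicing non-speech TE tasks — detecting amplitude
modulation (AMD) or discriminating AM rates (AMRD) — transfer to vocoded
consonant identification?

`vocotrain` implements the complete computational apparatus of such a
training study, and exercises it end to end on *simulated* observers: the
vocoder and stimulus synthesis, the adaptive psychophysics, threshold
estimation with quality control, Miller–Nicely information-transfer (IT)
analysis of consonant confusions, and the group-assignment and mixed-model
analysis scaffolding. No human data are collected or shipped; everything the
analysis pipeline consumes is produced by the package's own generators with
known ground truth.

## The vocoder

The analysis range 100–7800 Hz is divided into six contiguous bands of equal
width on the ERB~N~-number scale,
$E(f) = 21.4\,\log_{10}(0.00437 f + 1)$,
so that bands occupy roughly equal cochlear extents. Adjacent bands share
corner frequencies (the 3-dB points); each carrier sits at the geometric
(logarithmic) center $\sqrt{f_{lo} f_{hi}}$ of its band.

```{r}
design_filterbank(vocoder_config())
```

Design choices where the procedure leaves freedom:

* **Filter family.** "24 dB/octave" names a slope, not a filter. We use
  Butterworth filters of order `rolloff/6` (4th order here), applied
  forward–backward (`filtfilt`) so that channel envelopes stay time-aligned
  across bands. Zero-phase filtering doubles the magnitude slope; the
  single-pass response is available (`zero_phase = FALSE`) and is what the
  magnitude-response tests measure.
* **Envelope extraction.** Half-wave rectification followed by a 45-Hz,
  24-dB/octave lowpass — classic vocoder practice. An analytic-signal
  (Hilbert) envelope is available behind `envelope_method = "analytic"`;
  it avoids the rectifier's harmonic distortion and is used in tests that
  measure envelope attenuation above the cutoff.
* **Level matching.** The recombined output is rescaled to the input's
  overall RMS (`level_match = "total"`); per-channel matching is available.
* **Carrier phase** starts at zero in every channel: determinism aids
  testing and phase is perceptually irrelevant here.
* The first band's geometric center (182 Hz) is what the package reports;
  it is not forced to any externally quoted value, and centers of the other
  bands follow the same rule.

Sampling is whatever the input uses (stimuli default to 22.05 kHz); there is
no resampling step.

## Stimuli

AM tones are a 1-kHz carrier multiplied by a DC-shifted sinusoid
$[1 + m\sin(2\pi f_m t + \varphi)]$, with 10-ms raised-cosine ramps and
500-ms total duration. Because modulation adds sideband power, every AM tone
is divided by $\sqrt{1 + m^2/2}$ so its steady-state RMS equals the
unmodulated carrier's — otherwise overall loudness would betray the target
interval. The modulator phase $\varphi$ is drawn uniformly per interval.
Digital levels are expressed in dB re full scale; the nominal 70 dB SPL
presentation level of a real experiment is a playback calibration constant
with no digital counterpart. Frequency-discrimination (FD) stimuli are
100-ms, 800-Hz tones, the target raised by $\Delta f$ percent; tone pairs
are amplitude-equated. Whether the modulator is sine- or cosine-referenced
is immaterial once its phase is randomized; we use sine.

## Adaptive staircases

All three tasks share one two-phase transformed up-down rule in a 3I-3AFC
oddball design (chance = 1/3):

| task | tracked level | start | phase-1 factor | phase-2 factor |
|------|--------------|-------|----------------|----------------|
| AMD  | modulation depth $m$ | 1.0 (cap) | 1.58 (4 dB) | 1.26 (2 dB) |
| AMRD | rate increment $\Delta f_m$ (Hz) | 50% of the standard (4 Hz at 8 Hz) | 1.4 | $\sqrt{1.4}$ |
| FD   | frequency increment $\Delta f$ (Hz) | 50% (400 Hz) | 2 | $\sqrt 2$ |

Phase 1 is one-down/one-up; at the *first* incorrect response the track
switches permanently to three-down/one-up with the smaller factor,
converging on the level where $p^3 = 1/2$, i.e. $p \approx 79.4\%$ correct.
Details the procedure leaves open, decided once here:

* The consecutive-correct counter resets after every level change
  (standard transformed up-down bookkeeping).
* FD's phase-2 down-up rule is not stated explicitly; three-down/one-up is
  assumed for symmetry with the AM tasks.
* Levels clamp at a floor and cap rather than terminating the track; AMD's
  cap is $m = 1$. AMRD's cap is set at twice the standard rate and FD's at
  100% of the base frequency — generous ceilings that keep a guessing
  observer's track finite.
* The AMRD track variable is $\Delta f_m$ in Hz; multiplicative steps act on
  it directly, and observers see the level normalized by the standard
  ($\Delta f_m / f_m$), which makes the multiplicative staircase additive in
  $\log_{10}$ units. FD is normalized by the 800-Hz base, AMD by 1.
* Five practice trials (three easy at the start level, two impossible at
  zero) are flagged `practice`, presented at fixed levels outside the
  adaptive rule, and excluded from analysis.
* One seeded generator per track drives target intervals and observer
  responses in a fixed draw order, so every track is reproducible.

Training schedules deliver 21 blocks of 60 trials (9 on day 2, 12 on
day 3; 1260 trials in total), the standard rate rotating over 4, 8 and
16 Hz through rows of a 3×3 Latin square. Within any aligned 3-block cycle
each rate appears exactly once; the particular square realized for a given
participant in the original procedure is unrecoverable, so any valid square
is acceptable and the package fixes one.

## Simulated observers

An observer is a four-parameter psychometric function in $\log_{10}$ level,
$p(x) = \gamma + (1-\gamma-\lambda)\,\Phi\!\big(\beta(\log_{10}x-\alpha)\big)$,
with guess rate $\gamma = 1/3$, lapse rate $\lambda$ (default 0.02), slope
$\beta$ (default 8 per decade — a moderate psychometric slope) and location
$\alpha$. Study-level defaults place baseline thresholds at
$\alpha = -1.1$ (AMD, $m \approx 0.08$), $-0.7$ (AMRD,
$\Delta f_m/f_m \approx 0.2$) and $-1.8$ (FD, $\Delta f/f \approx 1.6\%$),
values typical of normal-hearing listeners on these tasks, with a
between-subject SD of 0.25 $\log_{10}$ units split between a shared
"good listener" component and task-specific variation — this split is what
produces the strong block-1/block-2 threshold correlations the consistency
checks look for.

Pre-to-post threshold improvements (in $\log_{10}$ units) are injected per
group × task; the defaults make each trained group improve most on its own
task (0.21 on AMD for AMD-trained, 0.23 on AMRD for AMRD-trained), with
smaller nonspecific gains elsewhere and the control group's largest gain on
FD (0.18) — the transfer structure the analysis pipeline is meant to detect.

## The VCV response generator

Consonant identification is simulated at the phonetic-feature level. Each of
the 20 consonants carries three features — voice (voiced/voiceless, 12/8),
manner (nasal, fricative, approximant, plosive-initial) and place (front,
middle, back) — shipped as an editable TSV. On each trial every feature of
the presented consonant survives independently with its transmission
probability $t$, else it is resampled uniformly from the feature's *other*
categories. A token whose three features all survive is identified
outright; otherwise the listener knows only the corrupted category triple
and guesses uniformly among the consonants consistent with it (uniformly
over all 20 when no consonant matches — the 20 consonants occupy only some
of the 24 possible triples).

Two modelling simplifications are deliberate: features are corrupted
independently (real confusions correlate them; a `resample` hook accepts a
function that rewrites the sampled categories jointly), and vowel context
is ignored, as the IT analysis collapses across /a/, /i/, /u/ anyway.
The generator's feature-transmission defaults (voice 0.97, manner 0.97,
place 0.75 at test sessions, reduced on the logit scale during
pre-training, with per-group logit gains of 0.30–0.42 from pre- to
post-test) were chosen once so that the simulated feature reception and its
improvement sit in the range reported for tone-vocoded consonant work —
manner received best, then voice, with place far worse; they are conditions
of the simulation, not fitted quantities.

## Threshold estimation and QC

Tracks are fitted by maximum likelihood with $\gamma = 1/3$ and $\lambda$
fixed at 0.01 (a sensitivity switch allows 0 and 0.05); only location and
slope are free, the slope deliberately unconstrained in sign. The reported
threshold is the fitted 79.4%-correct point, matching the staircase target;
the midpoint of $\Phi$ is recoverable from the returned parameters. Fits
with negative slope or with a threshold outside the range of levels the
track visited are invalid and discarded; subjects left without any valid
track in a task × session cell are flagged for exclusion. Surviving
$\log_{10}$ thresholds are screened once (no re-application) with a
2.5 × IQR fence within group × task × session, quartiles by linear
interpolation between order statistics (R's default type 7). Session-level
thresholds are the mean of the two block thresholds after QC; the per-track
records keep `block` as a column so block can instead enter the model as a
covariate. Numerical details: the likelihood is maximized by Nelder–Mead
from three starts (slopes 5, 15 and −5), probabilities are clamped away
from 0/1 by 10⁻⁹, and "outside the measure range" is implemented as outside
the [min, max] of visited levels.

## Information transfer

For a confusion matrix with counts $n_{ij}$,
$T = \sum_{ij} \frac{n_{ij}}{n}\log_2\frac{n\,n_{ij}}{n_i n_j}$ — the
plug-in mutual information. Feature-level matrices are obtained by summing
counts within categories. Because features differ in category number and in
priors (e.g. 12 voiced vs 8 voiceless), raw $T$ values are not comparable;
the package reports relative IT, $100\,T/H_{\text{in}}$, normalizing by the
stimulus entropy. The plug-in estimator is biased upward in small samples;
no correction is applied by default (a Miller–Madow flag exists) so that
estimates remain comparable with the uncorrected analyses standard in this
literature.

## Group assignment and models

Subjects are pre-assigned round-robin and re-routed while arriving: a
baseline (second pre-training block) score below every current group mean
sends the subject to the highest-mean group, above every mean to the
lowest-mean group — "considerably lower/higher" is operationalized minimally
as *outside the [min, max] of current group means*, with moves capped so
group sizes stay equal, and a final balance check (default tolerance 5
percentage points).

The model contract constructs `outcome ~ group * test (+ feature) +
control + (1 + test | subject)` and delegates estimation: linear outcomes
to `lmerTest` (Satterthwaite df), binary outcomes to `glmer` (Wald z,
asymptotic CIs), Type-III tests to `car::Anova`, and contrasts to
`emmeans`. If the maximal random structure fails to converge or is
singular, the model is refitted with random intercepts only and the
simplification is logged. Bayes-factor comparisons are out of scope: they
depend on the original human data and an unstated prior.

## What passing tests do and do not show

The simulation reproduces the *structure* of the study — its stimuli,
procedures, schedules and analysis path — and validates them against
independent oracles: closed-form filter responses, a brute-force Markov
stationary distribution for the staircase, an entropy-decomposition oracle
for IT (exhaustive over all small count matrices), and exact enumeration of
the VCV generative process. Problem sizes are chosen for desk-scale runs:
500 tracks × 100 trials for convergence estimates, 1000 tracks for the
Markov comparison, 200 tracks for threshold-recovery bias, 200 replicate
studies (threshold-record mode) for null calibration, and studies of 4–18
subjects per group elsewhere.

None of this licenses claims about human listeners: simulated observers
have stationary psychometric functions (no attention lapses beyond a
constant rate, no learning within a track), feature corruption is
independent and vowel-free, and the injected group effects are exactly the
sizes asked of the recovery analyses. The package demonstrates that *if*
listeners behaved like its observers, the pipeline would measure them
faithfully — which is precisely what a simulation scaffold is for.

## A worked example

```{r, eval = FALSE}
library(vocotrain)

# a small end-to-end study
pl <- run_study_pipeline(study_design(n_per_group = 8), seed = 77)
pl$contrasts$AMD        # per-group pre-to-post improvement on AMD
pl$it[1:6, ]            # per-subject relative IT by feature

# one adaptive track, fitted
obs <- observer_model(alpha = -1.1, beta = 8)
tr <- run_track(staircase_config("AMD"), obs, seed = 3, n_trials = 60)
plot(tr)
fit_track(tr)

# vocode an AM tone
y <- vocode(make_am_tone(fm = 8, m = 1), vocoder_config())
```
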
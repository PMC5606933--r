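---
title: "Methods: decoding reach kinematics from low-channel-count ECoG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding reach kinematics from low-channel-count ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A brain-machine interface for arm movement needs two things from motor-cortex
recordings: a reliable detector of *when* a movement starts and stops, and a
continuous readout of *how* the arm moves. `reachdec` implements both for
eight-contact epidural ECoG over the sensorimotor cortex, together with the
per-subject spectral mapping that makes the detector work, and a seeded
simulator that provides ground truth for every stage.

The pipeline mirrors a classical reach experiment: seated reaches from the lap
to targets left, middle and right of the midline (`RTL`, `RTM`, `RTR`), cued
by an auditory GO signal, with 6-8 s randomized rests, at least 40 trials per
target; ECoG/EEG/EMG sampled at 1200 Hz (0.1-500 Hz band), 3-D hand velocity
at 40 Hz; movement onset defined by the EMG crossing 3 standard deviations of
its rest baseline.

# Models

## ERD/ERS mapping and band selection

Trials are epoched from 4 s before to 8 s after the EMG onset. A short-time
Fourier spectrogram (0.5-s Hamming windows stepped by 10 ms, zero-padded to a
1-Hz bin grid — the only way a 0.5-s window yields 1-Hz bins) is averaged over
trials and each frequency row is expressed as percent change relative to the
pre-movement baseline (the 500-ms window from -2.0 to -1.5 s before onset):

\[ \mathrm{pct}(f,t) = 100 \cdot \frac{\bar P(f,t) - \bar P_b(f)}{\bar P_b(f)}. \]

Movement suppresses alpha-beta power (ERD) and boosts a subject-specific
narrow gamma band (ERS). The subject's band is the 4-Hz band centered on the
frequency with the largest mean percent change over the first movement
second; the half-max band is the contiguous run of bins at or above 50% of
the peak response. Bin-wise two-sample Kolmogorov–Smirnov tests (movement
values vs pooled baseline-window values across trials) provide significance;
the reported p-values are deliberately unadjusted, but the internal
"is the selected band responsive at all" gate Bonferroni-corrects across the
bins it checks — without that correction a pure-noise recording would pass
the gate almost surely.

## Movement-onset detection

The detection signal is the bipolar trace `ECOG1 - ECOG0` (adjacent contacts
over the hand motor area; the difference cancels common-mode noise). Band
power in the selected 4-Hz gamma band is computed in 200-ms windows stepped
every 50 ms; windows are labelled movement/rest from the EMG bursts; a Fisher
linear discriminant on `log10` band power is trained on the first 10 trials
and applied to the continuous remainder. A state flip requires two
consecutive agreeing windows (debounce); the resulting step function is the
gate `h(t)` of the decoder. Detection is scored at the event level:
a detection within ±500 ms of an EMG onset is a true positive (±500 ms is
half the minimum inter-movement gap), and

\[ F_1 = \frac{2\,TP}{2\,TP + FP + FN}. \]

The documented window-level chance F1 for a label-independent predictor with
MOVE prevalence $p$ is $2pq/(p+q) \le 2p/(1+p)$.

## Gated, lagged velocity decoding

The feature vector `E(t)` has 24 rows: the 8 raw ECoG channels, their 8
alpha-beta envelopes and their 8 gamma envelopes (envelope = zero-phase
band-pass, full-wave rectification, zero-phase 5-Hz low-pass). Velocity is a
gated, lagged multiple linear regression

\[ K(t) = b + \sum_{u} h(t-u)\,E(t-u)\,\beta(u) + \eta(t), \]

with 6 lag taps at the native ECoG sample interval (spanning 5 ms) delayed by
a cortico-kinematic lag `t0`. Anti-alias filtering commutes with lagging, so
each feature row is low-pass filtered once (0.8 x the kinematics Nyquist) and
every tap is pure indexing on the 40-Hz kinematics clock. Fitting is ordinary
least squares over gated samples only, and the prediction is defined as
exactly zero where the gate is closed (rest velocity is truly zero, so the
intercept never leaks into rest).

Two numerical points deserve emphasis:

* **Collinear taps.** After anti-alias filtering, taps spaced 0.83 ms apart
  are linearly dependent to near machine precision on the 40-Hz clock. The
  solver therefore uses a minimum-norm SVD pseudo-inverse (relative tolerance
  1e-10) over the tap subspace, and reserves the hard "rank-deficient design"
  error for genuine problems — duplicate or constant channels — detected on
  the single-tap design. An optional ridge penalty is available but off by
  default (the method is plain least squares).
* **Delay search.** The delay is found by maximising the leave-one-trial-out
  mean Pearson correlation over a 50-200 ms grid in 5-ms steps (the grid
  extends below the physiological 100-ms anchor so smaller simulated lags
  stay recoverable). The search model uses a *single* lag tap: with the full
  collinear 6-tap block the objective is nearly flat in `t0` (the block can
  re-time itself internally) and its maximum sits at the block center rather
  than the true lag — a 2-4 ms bias that is material on a 5-ms grid. The
  decoder itself is then fitted with all 6 taps at the chosen delay.

Accuracy is evaluated by leave-one-trial-out Pearson correlation on gated
samples, per direction, per axis (mean over axes by default; the Euclidean
*speed* correlation is used for cross-direction transfer, where per-axis
signs are not comparable).

## Duration regression

Per trial, the gamma "activity duration" is the contiguous time the
baseline-corrected band envelope stays above 50% of its per-trial peak
*increase* (run containing the peak). Two estimator details matter for an
unbiased duration: the envelope is smoothed at 2 Hz for this measurement so
ripples do not truncate the run inward, and the "peak" is the median of the
top 20% of the response rather than the raw maximum — a noise-inflated
maximum raises the threshold and systematically shortens the run. The 50%-of-raw-peak
reading is inoperable at realistic effect sizes: for ERS below +300% the
envelope multiplier is below 2, so half the raw peak falls at or below the
rest level and the "duration" would be unbounded. EMG duration comes from
the 3-SD burst detector. Both a free-intercept and a through-origin OLS line
are fitted; the through-origin R² is computed about the origin (uncentered),
and confidence bounds are normal-theory 95% intervals.

# The synthetic world

No recordings are distributed with the original study, so the package ships a
generative model with known ground truth. Per ECoG channel:

* **Background**: 1/f-spectrum noise (flat below 0.5 Hz, band-limited to the
  0.1-500 Hz amplifier band), 10 uV RMS.
* **Narrowband components** (one alpha-beta, one gamma): a shared cortical
  source seen by each contact with fixed, mixed-sign gains (so the bipolar
  pair sees it with unit gain). Each source is an amplitude-stable tone with
  slowly drifting phase plus a Gaussian spectral "skirt" carrying the
  configured bandwidth, plus two weak *unmodulated* satellite lines at
  ±3 Hz. During movement the tone+skirt amplitude is multiplied by a
  calibrated factor; the modulation window leads the EMG by the
  cortico-kinematic lag, has per-trial edge jitter (sd 0.15 s truncated
  at ±0.25 s — band activity does not track the EMG exactly, which gives
  the duration regression its realistic scatter, but stays within the
  event-matching tolerance), and Gaussian transitions (sd 0.2 s).
* **Slow component**: the lag-advanced linear readout
  `slow_c(t) = sum_a beta[c,a] v_a(t + lag)` of the 3-D minimum-jerk
  velocity through a fixed encoding matrix (`slow_gain = 3` uV/(cm/s) row
  scale, chosen so slow-potential excursions stay in the physiological
  ~100-200 uV range while dominating the sub-2-Hz background).

EMG is amplitude-modulated noise (burst = 10 x baseline, 150-ms rise);
kinematics are the minimum-jerk speed profile
`v(t) = (D/T)(30*tau^2 - 60*tau^3 + 30*tau^4)` times a 3-D direction unit
vector, plus white observation noise at 10% of each axis's RMS movement
amplitude (one scale per axis and session, like a real motion-capture
sensor). All three direction vectors have nonzero lateral, forward and
vertical components — lap-to-chest reaches are genuinely 3-D, and an exactly
axis-aligned direction would make that axis's correlation undefined.

Three calibration choices are worth spelling out, because they are forced by
the published numbers rather than free dials:

1. **Effect-size calibration.** The measured percent change at the band
   center is pinned analytically: given the tone/skirt/background split, the
   movement multiplier is solved so that the spectrogram-measured ERS/ERD on
   the *bipolar* trace equals the configured per-participant value
   (e.g. +281% gamma, -87% alpha-beta for participant 1). The tone's
   coherent gain through the Hamming estimator is computed exactly.
2. **Amplitude-stable carriers.** The printed ERS pins the movement/rest
   power ratio in the selection band at `1 + ERS/100` (2.1-3.8x). A purely
   Gaussian narrowband process observed through a 4-Hz filter in 200-ms
   windows has ~1.6 degrees of freedom per power estimate; at those ratios
   window-level classification would be far too noisy for the reported
   near-perfect F1. Near-perfect window separability at the printed effect
   sizes therefore *requires* the rest-state in-band power to be dominated
   by an amplitude-stable rhythm; the generator keeps stochastic in-band
   components below ~1% of the stable power (tone_rel = 300,
   skirt_rel = 0.25), which puts the window-power CV near 8% and the class
   separation above four standard deviations. This is a statement about the
   world implied jointly by the printed ERS values and F1 scores, not a
   tuning knob.
3. **Satellite lines.** Every bin within the Hamming kernel's mainlobe of a
   dominant modulated line inherits the line's percent change, so the ERD/ERS
   peak would be a 6-bin plateau whose argmax is decided by leakage jitter.
   The two unmodulated satellites (power = 3 x the kernel-leakage floor at
   ±3 Hz) pin the percent-change maximum to the configured center without
   affecting band-power stability (the 4-Hz Butterworth rejects them). A
   consequence: on preset sessions the measured half-max extent reflects the
   kernel, not the configured Table-style spectral width; the half-max
   recovery test therefore uses a skirt-only construction with a numerically
   computed expected extent.

## What a green test does and does not establish

The simulator reproduces: the protocol timing and trial counts, the printed
per-participant peak frequencies and ERD/ERS magnitudes as *measured by this
package's own estimators*, near-perfect event-level onset detection, a linear
cortico-kinematic readout with a recoverable 100-150 ms lag, duration
coupling between gamma bursts and EMG with realistic scatter, and shared or
direction-specific encodings for the transfer analyses. It does not attempt:
biophysical (dipole/forward-model) realism, cross-channel correlated
background, non-stationary drifts, artifacts other than frontal-EEG blinks,
broadband movement gamma, or any claim that real ECoG is an amplitude-stable
tone. Green acceptance tests establish that the *method* recovers the stated
effects in a world that matches the published effect sizes — not that it
would achieve the same numbers on other recordings.

# Tunable parameters

| Parameter | Default | Units | Where | Why this default |
|---|---|---|---|---|
| epoch window | -4 / +8 | s | `extract_trials` | stated trial definition |
| baseline | [-2, -1.5] | s | `erders` | stated baseline window |
| spectrogram | 0.5 s Hamming, 10 ms hop, 1-Hz bins | | `spectrogram` | stated analysis |
| selection band width | 4 | Hz | `select_band` | stated band width |
| movement interval | [0, 1] | s | `select_band`, `bandwidth_ratio_curve` | matches the bandwidth-ratio definition |
| EMG threshold k | 3 | baseline SD | `detect_emg_onsets` | stated rule |
| EMG smoothing | 100 | ms | `detect_emg_onsets` | standard burst detection |
| burst merge gap | 250 | ms | `detect_emg_onsets` | one reach = one burst |
| detector windows | 200 / 50 | ms | `band_power_windows` | stated windows; 50-ms *step* (the stated "overlap" is ambiguous; the reported 20-30 ms latencies need a fine hop) |
| training trials | 10 | trials | `detect_session_onsets` | stated training set |
| debounce | 2 | windows | `detect_onsets` | chatter suppression |
| TP tolerance | 500 | ms | `detect_onsets` | half the minimum inter-movement gap |
| blink threshold | 5 | robust SD | `reject_blink_trials` | automated stand-in for visual inspection |
| decoder order | 6 | taps (5 ms) | `fit_decoder` | stated model degree |
| delay grid | 50-200 by 5 | ms | `search_delay` | stated step and anchor, extended downward |
| envelope low-pass | 5 | Hz | `envelope` | stated envelope detector |
| duration envelope low-pass | 2 | Hz | `measure_band_durations` | crossing stability (see above) |
| ridge | 0 | | `fit_decoder` | plain least squares, optional rescue |

# Known limitations

* The onset classifier's default feature set is the gamma band only (it is
  the best single indicator); delta/beta features can be added via
  `extra_bands` but are not tuned.
* Blink rejection is an amplitude rule, not an ocular-topography method; it
  stands in for visual inspection and is labelled as such.
* The KS significance map is unadjusted by design and therefore liberal; only
  the band-selection gate corrects for multiplicity.
* `make_report`'s pooled-direction model and transfer rows assume all three
  directions are present.
* EDF support is the minimal subset needed for this package's sessions (one
  rate, 1-s records, 16-bit).
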
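# reachdec

Decoding arm reaching movements from low-channel-count electrocorticographic
(ECoG) recordings.

`reachdec` is for neural engineers and motor-systems researchers who want a
tested, end-to-end reference implementation of a classical ECoG
brain–machine-interface pipeline on just eight epidural contacts:

1. **Per-subject spectral mapping** — trial-averaged, baseline-normalised
   spectrograms (ERD/ERS maps) with Kolmogorov–Smirnov significance, and
   selection of the subject-specific 4-Hz gamma/alpha-beta bands where the
   movement response peaks.
2. **Movement-onset detection** — Fisher linear discriminant on `log10` gamma
   band power in 200-ms windows (50-ms step), trained on the first 10 trials,
   applied to the continuous recording, scored by the event-level
   F1 = 2TP/(2TP+FP+FN) against EMG-defined onsets, and emitting the binary
   gate `h(t)`.
3. **Velocity reconstruction** — a gated, lagged multiple linear regression

   K(t) = b + Σᵤ h(t−u) E(t−u) β(u) + η(t)

   where `E(t)` stacks the 8 raw ECoG channels with their alpha-beta and
   gamma envelopes (24 rows), `u` runs over 6 lag taps spanning 5 ms behind a
   cortico-kinematic delay `t0` found by grid search (50–200 ms, 5-ms steps),
   and accuracy is the leave-one-trial-out Pearson correlation on gated
   samples.

Because no recordings are distributed with the original study, the package
includes a first-class, seeded session simulator with known ground truth
(minimum-jerk kinematics, calibrated per-participant spectral effect sizes,
a linear slow-potential encoding with a configurable lag). Every stage of the
pipeline is tested against that ground truth; see the methods vignette
(`vignettes/reach-decoding-methods.Rmd`) for the generative model and the
reasoning behind its calibration.

## Worked example

```r
library(reachdec)

# a synthetic session with participant-1 effect sizes:
# gamma ERS +281% at 155 Hz, alpha-beta ERD -87% at 22 Hz,
# 40 trials per direction, 100-ms cortico-kinematic lag
sim <- simulate_session(sim_preset(1, seed = 1))
rec <- sim$recording

# onset detection: train on the first 10 trials, score the remainder
gamma <- band_spec(155, width = 4, role = "GAMMA_ERS")
ons <- detect_session_onsets(rec, gamma, n_train = 10)
ons$report
#> $tp
#> [1] 110
#>
#> $fp
#> [1] 0
#>
#> $fn
#> [1] 0
#>
#> $f1
#> [1] 1
#>
#> $latency_mean_ms
#> [1] -146.9545
#>
#> $latency_sd_ms
#> [1] 142.3966
```

All 110 held-out movements are detected with no false alarms (F1 = 1; the
printed study range is 0.98-0.99). The negative latency reflects the
simulated cortical lead plus per-trial band-timing jitter: gamma rises about
100 ms before the EMG on average.

```r
# gated, lagged decoding with per-direction delay search + leave-one-out
ab <- band_spec(22, width = 4, role = "ALPHABETA_ERD")
trials <- extract_trials(rec, ons$emg$onsets)
trials <- reachdec::match_trials_to_bursts(trials, ons$emg)
fx <- build_features(rec, ab, gamma, resample = FALSE)
kt <- (seq_len(ncol(rec$kinematics)) - 1) / rec$rate_kin
gate <- reachdec::gate_signal(ons$gate, kt)
tid <- reachdec::trial_id_vector(trials, kt)
loo <- loo_evaluate(fx, rec$kinematics, gate, tid, trials$direction,
                    t0 = "auto")
loo$by_direction
#>        mean_r       sd_r direction
#> RTL 0.9776094 0.01219622       RTL
#> RTM 0.9400954 0.02791406       RTM
#> RTR 0.9749693 0.01669395       RTR
loo$delays
#> $RTL
#> [1] 0.1
#>
#> $RTM
#> [1] 0.105
#>
#> $RTR
#> [1] 0.105
```

Per-direction leave-one-out correlations are in the 0.94-0.98 range
(printed study range 0.80-0.95) and the delay search recovers the simulated
100-ms lag within one grid step.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "reachdec", package = "reachdec"))')
Rscript $CLI simulate --preset 1 --seed 7 --out session/  # EDF + TSV + truth
Rscript $CLI inspect session/
Rscript $CLI emg-onsets session/ --k 3
Rscript $CLI detect session/ --band 153:157 --report report.json
Rscript $CLI evaluate session/ --gamma 153:157 --alphabeta 20:24 \
        --out report.json
```

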
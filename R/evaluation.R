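# Cross-validated scoring, cross-direction transfer, pooled models, duration
# regressions, and the end-to-end session report.

#' Assign kinematics samples to trials
#'
#' Maps each sample time to the trial whose `[onset - pad, offset + pad]`
#' window contains it (`NA` outside all trials); defines the leave-one-out
#' folds for the decoder.
#'
#' @param trials A `trial_set` with `offset_time` attached (see
#'   [match_trials_to_bursts()]).
#' @param times Sample times in seconds (kinematics clock).
#' @param pad Slack around each movement in seconds (default 0.5).
#' @return Integer trial index per sample, `NA` outside trials.
#' @export
trial_id_vector <- function(trials, times, pad = 0.5) {
  if (is.null(trials$offset_time))
    stop("trials need EMG-measured offsets; run match_trials_to_bursts()")
  id <- rep(NA_integer_, length(times))
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_time[i]
    off <- trials$offset_time[i]
    id[times >= on - pad & times <= off + pad] <- i
  }
  id
}

#' EMG conditioning and burst detection for a session
#'
#' Band-passes the designated (first) EMG channel and runs the 3-SD burst
#' detector.
#'
#' @param rec A `session_recording`.
#' @param k Threshold in baseline standard deviations.
#' @param baseline_interval Movement-free interval in seconds.
#' @return An `emg_onsets` result.
#' @export
emg_pipeline <- function(rec, k = 3, baseline_interval = c(0, 4)) {
  emg <- bandpass_emg(rec$emg[1, ], rec$rate_ecog)
  detect_emg_onsets(emg, rec$rate_ecog, baseline_interval = baseline_interval,
                    k = k)
}

#' Attach EMG-measured offsets and durations to a trial set
#'
#' Matches each trial to the nearest detected EMG burst (within `tol`
#' seconds of its onset) and records the burst offset and duration.
#'
#' @param trials A `trial_set`.
#' @param emg An `emg_onsets` result.
#' @param tol Matching tolerance in seconds (default 0.3).
#' @return The `trial_set` with `offset_time` and `emg_duration` columns.
#' @export
match_trials_to_bursts <- function(trials, emg, tol = 0.3) {
  trials$offset_time <- NA_real_
  trials$emg_duration <- NA_real_
  for (i in seq_len(nrow(trials))) {
    j <- which.min(abs(emg$onsets - trials$onset_time[i]))
    if (abs(emg$onsets[j] - trials$onset_time[i]) <= tol) {
      trials$offset_time[i] <- emg$offsets[j]
      trials$emg_duration[i] <- emg$offsets[j] - emg$onsets[j]
    }
  }
  trials
}

#' Train and apply the movement-onset detector on a session
#'
#' Runs the full onset stage: bipolar derivation (default `ECOG1 - ECOG0`),
#' 4-Hz gamma band-power windows, EMG-derived labels, Fisher discriminant
#' trained on the first `n_train` trials, continuous detection over the
#' held-out remainder (scored against the EMG truth), and a whole-session
#' gate for the decoder.
#'
#' @param rec A `session_recording`.
#' @param gamma_band A [band_spec()] (4-Hz selection band).
#' @param n_train Training trials (default 10).
#' @param tol TP matching tolerance in seconds (default 0.5).
#' @param extra_bands Optional additional [band_spec()]s as features.
#' @return List: `model`, `report` (held-out `classification_report`),
#'   `gate` (whole-session MOVE intervals), `emg` (burst detection),
#'   `t_split`, `heldout_window_f1`, `move_prevalence`.
#' @export
detect_session_onsets <- function(rec, gamma_band, n_train = 10, tol = 0.5,
                                  extra_bands = NULL) {
  fs <- rec$rate_ecog
  ch <- bipolar_derivation(rec)
  emg <- emg_pipeline(rec)
  if (length(emg$onsets) <= n_train)
    stop("need more than n_train = ", n_train, " detected movements")
  bands <- c(list(gamma_band), extra_bands)
  feats <- label_windows(band_power_windows(ch, fs, bands), emg)
  t_split <- (emg$offsets[n_train] + emg$onsets[n_train + 1]) / 2
  model <- train_onset_lda(windows_in_time(feats, 0, t_split))
  heldout <- windows_in_time(feats, t_split)
  det <- detect_onsets(model, heldout,
                       true_onsets = emg$onsets[emg$onsets >= t_split],
                       tol = tol)
  full <- detect_onsets(model, feats)
  list(model = model, report = det$report, gate = full$gate, emg = emg,
       t_split = t_split,
       heldout_window_f1 = window_f1(det$pred, heldout$labels),
       move_prevalence = mean(feats$labels == "MOVE"))
}

#' Leave-one-trial-out decoder evaluation
#'
#' For each (optionally per-direction) trial: fit the gated lagged
#' regression on all other trials at the searched (or given) delay and
#' correlate the held-out prediction with the recorded velocity on gated
#' samples.
#'
#' @param fx A `feature_series`.
#' @param k Kinematics `[3 x n]`.
#' @param gate Logical gate on the kinematics clock.
#' @param trial_id Trial id per kinematics sample.
#' @param trial_dirs Direction label per trial (names/order = trial index).
#' @param per_direction Fit one model per reach direction (default TRUE).
#' @param t0 Delay in seconds, or `"auto"` to run [search_delay()].
#' @param order Lag taps (default 6).
#' @param grid Delay grid for `"auto"`.
#' @param rate_out Kinematics rate (default 40).
#' @param mode Correlation mode `"axes"` or `"speed"`.
#' @return List: `per_trial` (trial, direction, r), `by_direction`
#'   (mean/sd), `mean_r`, `delays` used.
#' @export
loo_evaluate <- function(fx, k, gate, trial_id, trial_dirs,
                         per_direction = TRUE, t0 = "auto", order = 6,
                         grid = seq(0.05, 0.2, by = 0.005), rate_out = 40,
                         mode = "axes") {
  rows <- prepare_lag_rows(fx, rate_out)
  groups <- if (per_direction) split(seq_along(trial_dirs), trial_dirs)
            else list(ALL = seq_along(trial_dirs))
  res <- NULL
  delays <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < 3) stop("need >= 3 trials per evaluated group")
    sel_gate <- gate & trial_id %in% ids
    use_t0 <- t0
    if (identical(t0, "auto")) {
      # delay search with the single-tap model (see search_delay details)
      mean_r <- vapply(grid, function(d)
        mean(loo_correlations(rows, fx$rate, k, sel_gate, trial_id, d,
                              1L, rate_out, mode)$r, na.rm = TRUE), 0)
      use_t0 <- grid[which(mean_r == max(mean_r))[1]]
    }
    delays[[g]] <- use_t0
    r <- loo_correlations(rows, fx$rate, k, sel_gate, trial_id, use_t0,
                          order, rate_out, mode)
    r$direction <- g
    res <- rbind(res, r)
  }
  by_dir <- do.call(rbind, lapply(split(res$r, res$direction), function(v)
    data.frame(mean_r = mean(v, na.rm = TRUE), sd_r = stats::sd(v))))
  by_dir$direction <- rownames(by_dir)
  list(per_trial = res, by_direction = by_dir,
       mean_r = mean(res$r, na.rm = TRUE), delays = delays)
}

#' Cross-direction transfer evaluation
#'
#' Fits the decoder on all trials of `train_dir` and correlates predicted
#' with recorded arm speed over the gated samples of `test_dir` trials
#' (speed-mode correlation, as used for the transfer analysis).
#'
#' @inheritParams loo_evaluate
#' @param train_dir,test_dir Direction labels (`train_dir == test_dir`
#'   reduces to in-sample evaluation).
#' @return Pearson correlation of predicted vs recorded speed.
#' @export
transfer_evaluate <- function(fx, k, gate, trial_id, trial_dirs, train_dir,
                              test_dir, t0 = 0.1, order = 6, rate_out = 40) {
  for (d in unique(c(train_dir, test_dir)))
    if (!d %in% trial_dirs) stop("direction not present in session: ", d)
  rows <- prepare_lag_rows(fx, rate_out)
  tr_ids <- which(trial_dirs == train_dir)
  te_ids <- which(trial_dirs == test_dir)
  model <- fit_decoder(fx, k, gate & trial_id %in% tr_ids, t0 = t0,
                       order = order, rate_out = rate_out, prepared = rows)
  sel <- gate & trial_id %in% te_ids
  pred <- predict_decoder(model, fx, sel, prepared = rows)
  safe_cor(sqrt(colSums(pred[, sel, drop = FALSE]^2)),
           sqrt(colSums(k[, sel, drop = FALSE]^2)))
}

#' Regression of band-activity duration on EMG duration
#'
#' Fits both a free-intercept OLS line and a through-origin line of `y`
#' (band-activity duration) on `x` (EMG-burst duration). The through-origin
#' R-squared is computed about the origin (uncentered:
#' `1 - RSS / sum(y^2)`). Confidence bounds are normal-theory 95\% OLS
#' intervals.
#'
#' @param x EMG-burst durations in seconds.
#' @param y Band-activity durations in seconds.
#' @return List with `free` (slope, intercept, their 95\% CIs, r2) and
#'   `origin` (slope, its 95\% CI, r2_uncentered), plus `n`.
#' @export
duration_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired durations")
  if (stats::sd(x) == 0) stop("zero-variance EMG durations")
  free <- stats::lm(y ~ x)
  cif <- stats::confint(free)
  orig <- stats::lm(y ~ 0 + x)
  cio <- stats::confint(orig)
  list(free = list(slope = unname(stats::coef(free)[2]),
                   intercept = unname(stats::coef(free)[1]),
                   slope_ci = unname(cif[2, ]),
                   intercept_ci = unname(cif[1, ]),
                   r2 = summary(free)$r.squared),
       origin = list(slope = unname(stats::coef(orig)[1]),
                     slope_ci = unname(cio[1, ]),
                     r2_uncentered = 1 - sum(stats::resid(orig)^2) /
                       sum(y^2)),
       n = length(x))
}

#' Per-trial band-activity and EMG durations
#'
#' Band-activity duration is the contiguous time the baseline-corrected band
#' envelope stays above 50\% of its per-trial peak increase (the run
#' containing the peak); the per-trial baseline is the envelope mean over
#' `[-2, -1.5]` s relative to onset. EMG durations come from the 3-SD burst
#' detector. See the methods vignette for why the 50\% threshold applies to
#' the baseline-corrected response rather than the raw envelope.
#'
#' @param rec A `session_recording`.
#' @param trials A `trial_set` with `offset_time`/`emg_duration` attached
#'   (see [detect_session_onsets()] / `match_trials_to_bursts`).
#' @param band A [band_spec()] (the gamma selection band).
#' @param search Window (seconds relative to onset) searched for the peak.
#' @param lp_cutoff Envelope smoothing cutoff in Hz; the default (2 Hz) is
#'   heavier than the decoder's 5-Hz envelope so that threshold crossings are
#'   not truncated inward by fast envelope ripples.
#' @return data.frame: `trial`, `direction`, `emg_duration`,
#'   `band_duration` (seconds).
#' @export
measure_band_durations <- function(rec, trials, band,
                                   search = c(-1, 6), lp_cutoff = 2) {
  fs <- rec$rate_ecog
  env <- envelope(bipolar_derivation(rec), fs, band, lp_cutoff = lp_cutoff)
  out <- data.frame(trial = seq_len(nrow(trials)),
                    direction = trials$direction,
                    emg_duration = trials$emg_duration,
                    band_duration = NA_real_)
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_time[i]
    bidx <- (round((on - 2) * fs) + 1):(round((on - 1.5) * fs))
    base <- mean(env[bidx])
    widx <- (round((on + search[1]) * fs) + 1):(round((on + search[2]) * fs))
    resp <- env[widx] - base
    pk <- which.max(resp)
    if (resp[pk] <= 0) next
    # plateau level = median of the top of the response; the raw max is
    # noise-inflated, which would bias the half-max run inward
    thr <- stats::median(resp[resp >= 0.8 * resp[pk]]) / 2
    lo <- pk; while (lo > 1 && resp[lo - 1] >= thr) lo <- lo - 1
    hi <- pk; while (hi < length(resp) && resp[hi + 1] >= thr) hi <- hi + 1
    out$band_duration[i] <- (hi - lo + 1) / fs
  }
  out
}

#' End-to-end session evaluation report
#'
#' Runs the complete pipeline on one session: EMG bursts, trial epoching,
#' blink rejection, onset detection (held-out F1 and latency), gated lagged
#' decoding with per-direction leave-one-out correlations, cross-direction
#' transfer, a pooled-direction model, and the gamma duration regressions.
#'
#' @param rec A `session_recording`.
#' @param gamma_band,alphabeta_band [band_spec()]s (selection bands).
#' @param n_train Onset-classifier training trials (default 10).
#' @param order Decoder lag taps (default 6).
#' @param grid Delay grid.
#' @param transfer_pair `c(train, test)` directions for the transfer row.
#' @return A nested list (JSON-serialisable) mirroring the detection /
#'   reconstruction-accuracy / duration-regression report structure.
#' @export
make_report <- function(rec, gamma_band, alphabeta_band, n_train = 10,
                        order = 6, grid = seq(0.05, 0.2, by = 0.005),
                        transfer_pair = c("RTR", "RTL")) {
  onset <- detect_session_onsets(rec, gamma_band, n_train = n_train)
  trials <- extract_trials(rec, onset$emg$onsets)
  trials <- reject_blink_trials(trials, rec)
  trials <- match_trials_to_bursts(trials, onset$emg)
  act <- active_trials(trials)
  fx <- build_features(rec, alphabeta_band, gamma_band, resample = FALSE)
  kt <- (seq_len(ncol(rec$kinematics)) - 1) / rec$rate_kin
  gate <- gate_signal(onset$gate, kt)
  tid <- trial_id_vector(act, kt)
  loo <- loo_evaluate(fx, rec$kinematics, gate, tid, act$direction,
                      order = order, grid = grid, rate_out = rec$rate_kin)
  pooled <- loo_evaluate(fx, rec$kinematics, gate, tid, act$direction,
                         per_direction = FALSE, order = order, grid = grid,
                         rate_out = rec$rate_kin)
  tr_r <- if (all(transfer_pair %in% act$direction)) {
    transfer_evaluate(fx, rec$kinematics, gate, tid, act$direction,
                      transfer_pair[1], transfer_pair[2],
                      t0 = loo$delays[[transfer_pair[1]]], order = order,
                      rate_out = rec$rate_kin)
  } else NA_real_
  dur <- measure_band_durations(rec, act, gamma_band)
  dreg <- duration_regression(dur$emg_duration, dur$band_duration)
  rep <- onset$report
  list(
    detection = list(f1 = rep$f1, tp = rep$tp, fp = rep$fp, fn = rep$fn,
                     latency_ms = list(mean = rep$latency_mean_ms,
                                       sd = rep$latency_sd_ms)),
    reconstruction = list(
      by_direction = loo$by_direction,
      mean_r = loo$mean_r,
      delays_s = loo$delays,
      pooled_r = pooled$mean_r,
      transfer = list(train = transfer_pair[1], test = transfer_pair[2],
                      r = tr_r)),
    duration_regression = list(
      band = "gamma ERS",
      slope = dreg$free$slope, intercept = dreg$free$intercept,
      r2 = dreg$free$r2,
      zero_intercept_slope = dreg$origin$slope,
      zero_intercept_slope_ci = dreg$origin$slope_ci,
      zero_intercept_r2 = dreg$origin$r2_uncentered,
      n = dreg$n),
    n_trials = nrow(trials), n_rejected = sum(trials$rejected))
}

#' Window-level chance F1
#'
#' Documented chance oracle: a label-independent classifier that predicts
#' MOVE with rate q attains window F1 `2pq/(p+q)` at MOVE prevalence p,
#' maximised at `2p/(1+p)` by always predicting MOVE.
#'
#' @param prevalence MOVE prevalence p in (0, 1).
#' @return The chance-level F1 upper bound `2p/(1+p)`.
#' @export
chance_f1 <- function(prevalence) 2 * prevalence / (1 + prevalence)
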
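# EMG conditioning, burst/onset labelling, and bipolar ECoG derivation.

#' Band-pass filter an EMG signal (20-500 Hz, zero phase)
#'
#' @param x Numeric EMG signal.
#' @param rate Sampling rate in Hz; must exceed 1000 Hz so that the 500-Hz
#'   upper edge is below Nyquist.
#' @param order Butterworth order (default 3).
#' @return Filtered signal.
#' @export
bandpass_emg <- function(x, rate, order = 3) {
  if (rate <= 1000) stop("EMG rate must exceed 1000 Hz for a 20-500 Hz band")
  bandpass_filtfilt(x, rate, 20, 500, order = order)
}

#' Detect EMG burst onsets and offsets
#'
#' The (already band-passed) EMG is full-wave rectified and smoothed with a
#' centred 100-ms moving average; a burst onset is an upward crossing of
#' `baseline_mean + k * baseline_sd` (statistics of the smoothed signal over
#' `baseline_interval`), the offset the matching downward crossing. Bursts
#' separated by less than `merge_gap` are merged. Onsets are strictly
#' increasing and each offset exceeds its onset.
#'
#' @param emg Numeric EMG signal (band-passed).
#' @param rate Sampling rate in Hz.
#' @param baseline_interval `c(start, end)` seconds known to contain no
#'   movement (the simulator's initial rest guarantees this).
#' @param k Threshold in baseline standard deviations (default 3).
#' @param merge_gap Minimum burst separation in seconds (default 0.25).
#' @param min_duration Minimum burst duration in seconds (default 0.1);
#'   shorter excursions are discarded as noise.
#' @return List of class `emg_onsets`: `onsets`, `offsets` (seconds),
#'   `baseline_mean`, `baseline_sd`, `threshold_used` (uV).
#' @export
detect_emg_onsets <- function(emg, rate, baseline_interval = c(0, 4), k = 3,
                              merge_gap = 0.25, min_duration = 0.1) {
  env <- smoothed_rectified(emg, rate)
  i0 <- max(1L, floor(baseline_interval[1] * rate) + 1L)
  i1 <- min(length(env), ceiling(baseline_interval[2] * rate))
  base <- env[i0:i1]
  mu <- mean(base); sdv <- stats::sd(base)
  if (sdv == 0) stop("zero-variance baseline; cannot set a threshold")
  thr <- mu + k * sdv
  above <- env > thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  if (length(starts) > 1) {  # merge bursts separated by < merge_gap
    keep_s <- starts[c(TRUE, (starts[-1] - ends[-length(ends)]) / rate >
                         merge_gap)]
    keep_e <- ends[c((starts[-1] - ends[-length(ends)]) / rate > merge_gap,
                     TRUE)]
    starts <- keep_s; ends <- keep_e
  }
  long_enough <- (ends - starts + 1) / rate >= min_duration
  starts <- starts[long_enough]; ends <- ends[long_enough]
  structure(list(onsets = (starts - 1) / rate, offsets = (ends - 1) / rate,
                 baseline_mean = mu, baseline_sd = sdv,
                 threshold_used = thr),
            class = "emg_onsets")
}

# Rectify + centred 100-ms moving average. Edge samples (half a window) keep
# the session-mean rectified level so they never produce spurious crossings.
smoothed_rectified <- function(x, rate, win_s = 0.1) {
  nw <- max(1L, round(win_s * rate))
  if (nw %% 2 == 0) nw <- nw + 1L
  v <- as.numeric(stats::filter(abs(x), rep(1 / nw, nw), sides = 2))
  v[is.na(v)] <- mean(abs(x))
  v
}

#' Bipolar derivation of two labelled channels
#'
#' Returns `signal - reference`, sample-wise; suppresses common-mode noise
#' shared by adjacent contacts.
#'
#' @param rec A `session_recording`.
#' @param signal_ch,reference_ch Channel labels (e.g. `"ECOG1"`, `"ECOG0"`).
#' @return Numeric signal.
#' @export
bipolar_derivation <- function(rec, signal_ch = "ECOG1",
                               reference_ch = "ECOG0") {
  get_channel(rec, signal_ch) - get_channel(rec, reference_ch)
}
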
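# Spectrogram estimation, ERD/ERS baseline normalisation, Kolmogorov-Smirnov
# significance maps, per-subject band selection, and bandwidth-discriminability
# curves.

#' Frequency band specification
#'
#' @param center Band center in Hz.
#' @param width Band width in Hz (selection bands default to 4 Hz).
#' @param role One of `"GAMMA_ERS"`, `"ALPHABETA_ERD"`, `"SLOW"`.
#' @param halfmax_band Optional `c(lo, hi)` Hz where the movement response
#'   stays above 50\% of its peak.
#' @param peak_pct Optional peak percent change.
#' @return A `band_spec` list with `lo`/`hi` edges derived from center/width.
#' @export
band_spec <- function(center, width = 4, role = "GAMMA_ERS",
                      halfmax_band = NULL, peak_pct = NA_real_) {
  if (width <= 0) stop("band width must be positive")
  structure(list(center = center, width = width, lo = center - width / 2,
                 hi = center + width / 2, role = role,
                 halfmax_band = halfmax_band, peak_pct = peak_pct),
            class = "band_spec")
}

#' Short-time Fourier spectrogram
#'
#' 0.5-s Hamming windows stepped by 10 ms. At 1200 Hz the native resolution
#' of a 0.5-s window is 2 Hz; windows are zero-padded to `rate` samples so
#' that bins fall on a 1-Hz grid (the only way a 0.5-s window yields 1-Hz
#' bins). Power is scaled to uV^2/Hz (one-sided periodogram normalisation).
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param window_s Window length in seconds (default 0.5).
#' @param hop_s Hop in seconds (default 0.01).
#' @param fmax Optional maximum frequency to retain (rows above are dropped).
#' @param t0 Time of the first sample of `x` (seconds); column times are
#'   window centers on this clock (trial-aligned maps use `t0 = -pre`).
#' @return A `tf_map`: list with `power` `[n_freqs x n_times]`, `freqs`,
#'   `times`, `window`.
#' @export
spectrogram <- function(x, rate, window_s = 0.5, hop_s = 0.01, fmax = NULL,
                        t0 = 0) {
  nw <- round(window_s * rate)
  if (length(x) < nw) stop("signal shorter than one analysis window")
  hop <- round(hop_s * rate)
  nfft <- max(nw, round(rate))  # zero-pad to 1-Hz bins
  starts <- seq(1, length(x) - nw + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  seg <- matrix(0, nfft, length(starts))
  for (j in seq_along(starts))
    seg[1:nw, j] <- x[starts[j]:(starts[j] + nw - 1)] * w
  sp <- stats::mvfft(seg)
  nf <- nfft %/% 2 + 1
  pw <- Mod(sp[1:nf, , drop = FALSE])^2 / (rate * sum(w^2))
  pw[2:(nf - 1), ] <- 2 * pw[2:(nf - 1), ]  # one-sided
  freqs <- (0:(nf - 1)) * rate / nfft
  if (!is.null(fmax)) {
    keep <- freqs <= fmax
    pw <- pw[keep, , drop = FALSE]
    freqs <- freqs[keep]
  }
  times <- t0 + (starts - 1 + (nw - 1) / 2) / rate
  structure(list(power = pw, freqs = freqs, times = times,
                 window = window_s), class = "tf_map")
}

# Spectrograms for one channel over all (active) trials, aligned to onset.
trial_spectrograms <- function(rec, trials, channel = NULL, fmax = 250) {
  trials <- active_trials(trials)
  if (is.null(channel)) channel <- bipolar_derivation(rec)
  lapply(seq_len(nrow(trials)), function(i) {
    n <- attr(trials, "n_ecog")
    i0 <- trials$start_ecog[i]
    spectrogram(channel[i0:(i0 + n - 1)], rec$rate_ecog, fmax = fmax,
                t0 = -attr(trials, "pre"))
  })
}

#' Baseline-normalised event-related spectral change (ERD/ERS)
#'
#' `pct_change(f, t) = 100 * (P(f, t) - Pb(f)) / Pb(f)` on trial-averaged
#' power, where `Pb(f)` is the mean power over the baseline interval
#' (default the 500-ms window from -2 to -1.5 s relative to movement onset).
#' With `per_trial = TRUE` each trial is normalised by its own baseline
#' before averaging.
#'
#' @param tfmaps List of aligned `tf_map`s (one per trial, identical grids).
#' @param baseline `c(start, end)` seconds on the maps' (onset-aligned) clock.
#' @param per_trial Normalise per trial instead of by the pooled baseline.
#' @return An `erders_map`: `pct_change` matrix, `freqs`, `times`,
#'   `baseline`, and `mean_power`/`baseline_power` kept for downstream use.
#' @export
erders <- function(tfmaps, baseline = c(-2, -1.5), per_trial = FALSE) {
  if (length(tfmaps) < 2) stop("need at least 2 trials")
  freqs <- tfmaps[[1]]$freqs; times <- tfmaps[[1]]$times
  bcols <- which(times >= baseline[1] & times < baseline[2])
  if (length(bcols) == 0) stop("baseline interval outside the trial window")
  if (per_trial) {
    acc <- 0
    for (m in tfmaps) {
      pb <- rowMeans(m$power[, bcols, drop = FALSE])
      if (any(pb == 0))
        stop("zero baseline power in bin ", freqs[which(pb == 0)[1]], " Hz")
      acc <- acc + m$power / pb
    }
    pbar <- acc / length(tfmaps)
    pb <- rowMeans(pbar[, bcols, drop = FALSE])
    pct <- 100 * sweep(sweep(pbar, 1, pb), 1, pb, "/")
    mean_power <- pbar
  } else {
    mean_power <- Reduce(`+`, lapply(tfmaps, `[[`, "power")) / length(tfmaps)
    pb <- rowMeans(mean_power[, bcols, drop = FALSE])
    if (any(pb == 0))
      stop("zero baseline power in bin ", freqs[which(pb == 0)[1]], " Hz")
    pct <- 100 * sweep(sweep(mean_power, 1, pb), 1, pb, "/")
  }
  structure(list(pct_change = pct, freqs = freqs, times = times,
                 baseline = baseline, mean_power = mean_power,
                 baseline_power = pb, n_trials = length(tfmaps)),
            class = "erders_map")
}

#' Kolmogorov-Smirnov significance of movement-related power changes
#'
#' For each retained (frequency, time) bin, a two-sample KS test compares the
#' across-trial distribution of power at that bin with the across-trial
#' distribution of mean baseline power at the same frequency. P-values are
#' unadjusted for multiple comparisons (deliberately matching the original
#' reporting; flagged as liberal).
#'
#' @param tfmaps List of aligned `tf_map`s (>= 2; >= 8 recommended).
#' @param baseline Baseline interval in seconds.
#' @param freq_range Optional `c(lo, hi)` restricting rows.
#' @param time_range Optional `c(lo, hi)` restricting columns.
#' @param col_step Evaluate every `col_step`-th retained column (default 1).
#' @return List with `p` matrix and the `freqs`/`times` it covers.
#' @export
ks_significance <- function(tfmaps, baseline = c(-2, -1.5),
                            freq_range = NULL, time_range = NULL,
                            col_step = 1) {
  if (length(tfmaps) < 2) stop("need at least 2 trials")
  freqs <- tfmaps[[1]]$freqs; times <- tfmaps[[1]]$times
  rows <- seq_along(freqs)
  if (!is.null(freq_range))
    rows <- rows[freqs[rows] >= freq_range[1] & freqs[rows] <= freq_range[2]]
  cols <- seq_along(times)
  if (!is.null(time_range))
    cols <- cols[times[cols] >= time_range[1] & times[cols] <= time_range[2]]
  cols <- cols[seq(1, length(cols), by = col_step)]
  bcols <- which(times >= baseline[1] & times < baseline[2])
  n_tr <- length(tfmaps)
  # baseline sample = all baseline-window values pooled across trials
  # (columns within a 0.5-s baseline window are strongly correlated, so the
  # effective sample size is closer to the trial count)
  base <- array(0, dim = c(length(rows), length(bcols), n_tr))
  for (k in seq_len(n_tr))
    base[, , k] <- tfmaps[[k]]$power[rows, bcols]
  p <- matrix(NA_real_, length(rows), length(cols))
  pw <- array(0, dim = c(length(rows), length(cols), n_tr))
  for (k in seq_len(n_tr)) pw[, , k] <- tfmaps[[k]]$power[rows, cols]
  for (i in seq_along(rows))
    for (j in seq_along(cols))
      p[i, j] <- suppressWarnings(
        stats::ks.test(pw[i, j, ], as.vector(base[i, , ]))$p.value)
  list(p = p, freqs = freqs[rows], times = times[cols])
}

#' Select a subject-specific frequency band from an ERD/ERS map
#'
#' The band center is the frequency with the largest mean percent change over
#' the movement interval (default `[0, 1]` s after onset), signed according
#' to `mode`; ties break toward the lower frequency. The selection band is
#' `center +/- 2` Hz; the half-max band is the contiguous run of bins around
#' the center whose response stays at or above 50\% of the peak. Percent
#' change is scale-free, so selection is invariant to signal scaling.
#'
#' @param map An `erders_map`.
#' @param search `c(lo, hi)` Hz search range.
#' @param mode `"ERS"` (maximal increase) or `"ERD"` (maximal decrease).
#' @param movement `c(start, end)` seconds defining the movement interval.
#' @param p_values Optional result of [ks_significance()] over (at least) the
#'   search range; when supplied, selection requires some bin in the search
#'   range and movement interval to reach `p < alpha`.
#' @param alpha Significance level for the gate (default 0.01).
#' @param width Selection band width in Hz (default 4).
#' @return A [band_spec()] with `halfmax_band` and `peak_pct` filled in.
#' @export
select_band <- function(map, search, mode = c("ERS", "ERD"),
                        movement = c(0, 1), p_values = NULL, alpha = 0.01,
                        width = 4) {
  mode <- match.arg(mode)
  rows <- which(map$freqs >= search[1] & map$freqs <= search[2])
  if (length(rows) == 0) stop("search range outside map frequencies")
  mcols <- which(map$times >= movement[1] & map$times <= movement[2])
  resp <- rowMeans(map$pct_change[rows, mcols, drop = FALSE])
  if (mode == "ERD") resp <- -resp
  best <- which(resp == max(resp))[1]  # ties -> lower frequency
  center <- map$freqs[rows[best]]
  if (!is.null(p_values)) {
    # The gate applies to the selected band with a Bonferroni-corrected
    # threshold over the bins it checks: the per-bin p-values themselves
    # stay unadjusted (and are reported as such), but an "is any bin
    # significant" gate without correction would fire on pure noise.
    pr <- which(p_values$freqs >= center - width / 2 &
                  p_values$freqs <= center + width / 2)
    pc <- which(p_values$times >= movement[1] & p_values$times <= movement[2])
    n_checked <- length(pr) * length(pc)
    if (n_checked == 0 ||
        min(p_values$p[pr, pc], na.rm = TRUE) >= alpha / n_checked)
      stop("no movement-responsive band: no bin of the selected band is ",
           "significant at p < ", alpha)
  }
  half <- resp >= resp[best] / 2
  lo_i <- best; while (lo_i > 1 && half[lo_i - 1]) lo_i <- lo_i - 1
  hi_i <- best; while (hi_i < length(resp) && half[hi_i + 1]) hi_i <- hi_i + 1
  band_spec(center, width = width,
            role = if (mode == "ERS") "GAMMA_ERS" else "ALPHABETA_ERD",
            halfmax_band = c(map$freqs[rows[lo_i]], map$freqs[rows[hi_i]]),
            peak_pct = if (mode == "ERS") resp[best] else -resp[best])
}

#' Movement/rest band-power ratio as a function of bandwidth
#'
#' For each width, the signal is zero-phase band-pass filtered with a
#' 3rd-order Butterworth at `center +/- width/2`; the per-trial ratio of mean
#' power in the movement second (`[0, 1]` s after onset) to the pre-movement
#' second (`[-1, 0]` s) is expressed in dB and averaged across trials.
#' A large ratio indicates good movement/rest discriminability; on a null
#' signal the ratio approaches 0 dB.
#'
#' @param x Numeric signal (e.g. a bipolar ECoG trace).
#' @param rate Sampling rate in Hz.
#' @param onsets Movement onset times in seconds.
#' @param center Band center in Hz.
#' @param widths Bandwidths in Hz (typically `seq(2, ..., by = 2)`).
#' @return data.frame with `width`, `ratio_db` (trial mean), `se_db`
#'   (standard error across trials).
#' @export
bandwidth_ratio_curve <- function(x, rate, onsets, center, widths) {
  if (any(center + widths / 2 >= rate / 2))
    stop("band exceeds Nyquist for the widest requested width")
  out <- lapply(widths, function(w) {
    filt <- bandpass_filtfilt(x, rate, center - w / 2, center + w / 2,
                              order = 3)
    p2 <- filt^2
    db <- vapply(onsets, function(on) {
      mov <- p2[(round(on * rate) + 1):(round((on + 1) * rate))]
      pre <- p2[(round((on - 1) * rate) + 1):(round(on * rate))]
      10 * log10(mean(mov) / mean(pre))
    }, 0)
    c(mean(db), stats::sd(db) / sqrt(length(db)))
  })
  data.frame(width = widths,
             ratio_db = vapply(out, `[`, 0, 1),
             se_db = vapply(out, `[`, 0, 2))
}
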
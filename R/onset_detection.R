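# Windowed band-power features, linear-discriminant movement classification,
# continuous onset detection with a gate signal, and F1/latency scoring.

#' Windowed band power features
#'
#' For each band: zero-phase 3rd-order Butterworth band-pass, then mean
#' squared amplitude in 200-ms windows stepped every 50 ms.
#'
#' @param x Numeric signal at `rate`.
#' @param rate Sampling rate in Hz.
#' @param bands List of [band_spec()]s (or a single one).
#' @param window_s Window length in seconds (default 0.2).
#' @param step_s Window step in seconds (default 0.05).
#' @param t0 Time of the first sample of `x` (seconds, session clock).
#' @return A `window_features` list: `times` (window centers), `power`
#'   `[n_bands x n_windows]` (uV^2), `labels` (NULL until
#'   [label_windows()]), `window_s`, `step_s`.
#' @export
band_power_windows <- function(x, rate, bands, window_s = 0.2,
                               step_s = 0.05, t0 = 0) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  nw <- round(window_s * rate); hop <- round(step_s * rate)
  starts <- seq(1, length(x) - nw + 1, by = hop)
  power <- matrix(0, length(bands), length(starts))
  for (b in seq_along(bands)) {
    bd <- bands[[b]]
    if (bd$hi >= rate / 2) stop("band above Nyquist: ", bd$hi, " Hz")
    xf <- bandpass_filtfilt(x, rate, bd$lo, bd$hi, order = 3)
    cs <- cumsum(c(0, xf^2))
    power[b, ] <- (cs[starts + nw] - cs[starts]) / nw
  }
  structure(list(times = t0 + (starts - 1 + (nw - 1) / 2) / rate,
                 power = power, labels = NULL,
                 window_s = window_s, step_s = step_s),
            class = "window_features")
}

#' Label windows as movement or rest from EMG bursts
#'
#' A window is `MOVE` iff its center lies inside any `[onset, offset]` burst.
#'
#' @param features A `window_features`.
#' @param emg An `emg_onsets` result (or a list with `onsets`, `offsets`).
#' @return `features` with `labels` filled in.
#' @export
label_windows <- function(features, emg) {
  lab <- rep("REST", length(features$times))
  for (i in seq_along(emg$onsets)) {
    lab[features$times >= emg$onsets[i] &
          features$times <= emg$offsets[i]] <- "MOVE"
  }
  features$labels <- lab
  features
}

# Subset of windows whose centers lie in [t_lo, t_hi).
windows_in_time <- function(features, t_lo = -Inf, t_hi = Inf) {
  keep <- features$times >= t_lo & features$times < t_hi
  features$times <- features$times[keep]
  features$power <- features$power[, keep, drop = FALSE]
  if (!is.null(features$labels)) features$labels <- features$labels[keep]
  features
}

#' Train a movement/rest linear discriminant on log band powers
#'
#' Fisher linear discriminant on `log10` band powers with the decision
#' threshold at the midpoint of the projected class means. Training data are
#' typically the labelled windows of the first 10 trials.
#'
#' @param features A labelled `window_features`.
#' @return An `onset_model`: `weights`, `threshold`, band count, class means.
#' @export
train_onset_lda <- function(features) {
  if (is.null(features$labels)) stop("features must be labelled first")
  y <- features$labels == "MOVE"
  if (!any(y) || all(y))
    stop("training windows contain a single class; cannot fit a discriminant")
  x <- t(log10(pmax(features$power, 1e-300)))
  mu1 <- colMeans(x[y, , drop = FALSE])
  mu0 <- colMeans(x[!y, , drop = FALSE])
  sw <- (crossprod(sweep(x[y, , drop = FALSE], 2, mu1)) +
           crossprod(sweep(x[!y, , drop = FALSE], 2, mu0))) / (nrow(x) - 2)
  sw <- sw + diag(1e-9, ncol(x))
  w <- solve(sw, mu1 - mu0)
  structure(list(weights = w,
                 threshold = sum(w * (mu1 + mu0)) / 2,
                 n_bands = ncol(x), mu_move = mu1, mu_rest = mu0,
                 trained = TRUE),
            class = "onset_model")
}

# Per-window MOVE decisions.
predict_windows <- function(model, features) {
  if (!isTRUE(model$trained)) stop("onset model is not trained")
  if (nrow(features$power) != model$n_bands)
    stop("feature band count differs from training")
  x <- t(log10(pmax(features$power, 1e-300)))
  drop(x %*% model$weights) > model$threshold
}

#' Detect movement onsets in continuous features
#'
#' Applies the trained discriminant per window and debounces the decision
#' sequence: a state flip requires `debounce` consecutive disagreeing
#' windows. An onset event is the time of the first window of a confirmed
#' MOVE run; the gate `h(t)` is 1 during MOVE runs (right-continuous step
#' function, returned as closed intervals). When EMG truth is supplied, a
#' detection within `tol` of a true onset is a TP (one-to-one nearest
#' matching), an unmatched detection an FP, an unmatched true onset an FN;
#' latency is detected minus true over TPs.
#'
#' @param model An `onset_model`.
#' @param features Continuous `window_features`.
#' @param true_onsets Optional EMG-defined onset times for scoring.
#' @param tol Matching tolerance in seconds (default 0.5, half the minimum
#'   inter-movement gap).
#' @param debounce Consecutive windows required to flip state (default 2).
#' @return List: `events` (onset times), `gate` (2-column matrix of MOVE
#'   intervals), `pred` (per-window logical), `report` (a
#'   `classification_report`, or NULL without truth).
#' @export
detect_onsets <- function(model, features, true_onsets = NULL, tol = 0.5,
                          debounce = 2) {
  pred <- predict_windows(model, features)
  times <- features$times
  n <- length(pred)
  state <- FALSE
  run <- 0L
  events <- numeric(0)
  gate_on <- numeric(0); gate_off <- numeric(0)
  pending_start <- NA_real_
  for (i in seq_len(n)) {
    if (pred[i] != state) {
      run <- run + 1L
      if (run == 1L) pending_start <- times[i]
      if (run >= debounce) {
        state <- !state
        run <- 0L
        if (state) {
          events <- c(events, pending_start)
          gate_on <- c(gate_on, pending_start)
        } else {
          gate_off <- c(gate_off, pending_start)
        }
      }
    } else {
      run <- 0L
    }
  }
  if (state) gate_off <- c(gate_off, times[n])
  gate <- cbind(on = gate_on, off = gate_off)
  report <- NULL
  if (!is.null(true_onsets)) {
    report <- match_events(events, true_onsets, tol)
  }
  list(events = events, gate = gate, pred = pred, report = report)
}

# One-to-one nearest matching of detections to true onsets within tol.
match_events <- function(events, truth, tol) {
  used <- rep(FALSE, length(events))
  latency <- numeric(0)
  tp <- 0L; fn <- 0L
  for (t0 in truth) {
    d <- abs(events - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
      latency <- c(latency, events[j] - t0)
    } else {
      fn <- fn + 1L
    }
  }
  fp <- sum(!used)
  structure(list(tp = tp, fp = fp, fn = fn,
                 f1 = if (2 * tp + fp + fn > 0) f1_score(tp, fp, fn)
                      else NA_real_,
                 latency_mean_ms = 1000 * mean(latency),
                 latency_sd_ms = 1000 * stats::sd(latency)),
            class = "classification_report")
}

#' F1 detection score
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, undefined (error) when all counts are 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  den <- 2 * tp + fp + fn
  if (den == 0) stop("F1 is undefined when TP = FP = FN = 0")
  2 * tp / den
}

# Window-level F1 of MOVE predictions against MOVE labels (used for
# chance-level analyses; the chance level under label-independent prediction
# with MOVE prevalence p is at most 2p/(1+p), attained by always-MOVE).
window_f1 <- function(pred, labels) {
  y <- labels == "MOVE"
  f1_score(sum(pred & y), sum(pred & !y), sum(!pred & y))
}

#' Sample gate intervals as a logical signal
#'
#' Evaluates the Heaviside gate `h(t)` (MOVE intervals from
#' [detect_onsets()]) at the given times.
#'
#' @param gate Two-column matrix of `[on, off]` interval times.
#' @param times Sample times in seconds.
#' @return Logical vector, `TRUE` inside any interval.
#' @export
gate_signal <- function(gate, times) {
  g <- rep(FALSE, length(times))
  if (is.null(gate) || nrow(gate) == 0) return(g)
  for (i in seq_len(nrow(gate)))
    g[times >= gate[i, 1] & times <= gate[i, 2]] <- TRUE
  g
}
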
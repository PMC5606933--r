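# Session container, on-disk layout, trial epoching and artifact rejection.

MARKER_KINDS <- c("GO", "EMG_ONSET", "EMG_OFFSET", "TRIAL_REJECT")
DIRECTIONS <- c("RTL", "RTM", "RTR", "NONE")

#' Multirate electrophysiology + kinematics session
#'
#' Bundles ECoG/EMG/EEG signals sampled at `rate_ecog`, 3-D kinematics sampled
#' at `rate_kin`, and event markers, with validation of the cross-stream
#' timing invariants. Time is in seconds from session start, sample indices
#' are 1-based (R convention), intervals are half-open `[start, end)`.
#'
#' @param ecog Matrix `[n_ecog x n_samples]`, microvolts.
#' @param emg Matrix `[n_emg x n_samples]`, microvolts.
#' @param eeg Optional matrix, microvolts, same rate and length as `ecog`.
#' @param kinematics Matrix `[3 x n_kin]`, cm/s, at `rate_kin`.
#' @param rate_ecog Sampling rate of ecog/emg/eeg in Hz (default 1200).
#' @param rate_kin Kinematics sampling rate in Hz (default 40).
#' @param markers `data.frame` with columns `time_s`, `kind`
#'   (GO / EMG_ONSET / EMG_OFFSET / TRIAL_REJECT), `direction`
#'   (RTL / RTM / RTR / NONE).
#' @param channel_labels List with character vectors `ecog`, `emg`, `eeg`.
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(ecog, emg, eeg = NULL, kinematics,
                              rate_ecog = 1200, rate_kin = 40,
                              markers = empty_markers(),
                              channel_labels = NULL) {
  ecog <- as.matrix(ecog); emg <- as.matrix(emg)
  kinematics <- as.matrix(kinematics)
  n <- ncol(ecog)
  if (ncol(emg) != n) stop("EMG sample count differs from ECoG")
  if (!is.null(eeg)) {
    eeg <- as.matrix(eeg)
    if (ncol(eeg) != n) stop("EEG sample count differs from ECoG")
  }
  if (nrow(kinematics) != 3) stop("kinematics must have 3 rows (vx, vy, vz)")
  dur <- n / rate_ecog
  dur_kin <- ncol(kinematics) / rate_kin
  if (abs(dur - dur_kin) > 1 / rate_kin + 1e-9)
    stop("kinematics duration (", dur_kin, " s) does not match signal ",
         "duration (", dur, " s) within one kinematics sample")
  markers <- validate_markers(markers, dur)
  if (is.null(channel_labels)) {
    channel_labels <- list(
      ecog = paste0("ECOG", seq_len(nrow(ecog)) - 1),
      emg = paste0("EMG_", seq_len(nrow(emg))),
      eeg = if (!is.null(eeg)) paste0("EEG_", seq_len(nrow(eeg))))
  }
  structure(list(ecog = ecog, emg = emg, eeg = eeg, kinematics = kinematics,
                 rate_ecog = rate_ecog, rate_kin = rate_kin,
                 markers = markers, channel_labels = channel_labels),
            class = "session_recording")
}

empty_markers <- function() {
  data.frame(time_s = numeric(0), kind = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

validate_markers <- function(markers, duration) {
  stopifnot(all(c("time_s", "kind", "direction") %in% names(markers)))
  if (nrow(markers) == 0) return(markers)
  if (any(markers$time_s < 0) || any(markers$time_s > duration))
    stop("marker times must lie within [0, duration]")
  if (!all(markers$kind %in% MARKER_KINDS))
    stop("unknown marker kind: ",
         paste(setdiff(markers$kind, MARKER_KINDS), collapse = ", "))
  if (!all(markers$direction %in% DIRECTIONS))
    stop("unknown direction label")
  go <- markers$kind == "GO"
  if (any(markers$direction[go] == "NONE"))
    stop("GO markers must carry a reach direction")
  markers[order(markers$time_s), , drop = FALSE]
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording>\n")
  cat(sprintf("  duration : %.1f s\n", ncol(x$ecog) / x$rate_ecog))
  cat(sprintf("  ECoG     : %d ch @ %g Hz\n", nrow(x$ecog), x$rate_ecog))
  cat(sprintf("  EMG      : %d ch @ %g Hz\n", nrow(x$emg), x$rate_ecog))
  if (!is.null(x$eeg))
    cat(sprintf("  EEG      : %d ch @ %g Hz\n", nrow(x$eeg), x$rate_ecog))
  cat(sprintf("  kinematics: 3 axes @ %g Hz\n", x$rate_kin))
  cat(sprintf("  markers  : %d (%s)\n", nrow(x$markers),
              paste(names(table(x$markers$kind)), table(x$markers$kind),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

session_duration <- function(rec) ncol(rec$ecog) / rec$rate_ecog

# Look up a signal channel by label across the ecog/emg/eeg groups.
get_channel <- function(rec, label) {
  for (grp in c("ecog", "emg", "eeg")) {
    labs <- rec$channel_labels[[grp]]
    if (!is.null(labs) && label %in% labs)
      return(rec[[grp]][match(label, labs), ])
  }
  stop("unknown channel label: ", label)
}

#' Save a session to a directory
#'
#' Writes `signals.edf` (all same-rate channels, 16-bit), `kinematics.tsv`
#' (`time_s, vx, vy, vz`) and `markers.tsv` (`time_s, kind, direction`).
#'
#' @param rec A `session_recording`.
#' @param dir Output directory (created if needed).
#' @param physical_range Passed to [write_edf()]; default scales per channel.
#' @return `dir`, invisibly.
#' @export
save_session <- function(rec, dir, physical_range = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- rbind(rec$ecog, rec$emg, if (!is.null(rec$eeg)) rec$eeg)
  labels <- c(rec$channel_labels$ecog, rec$channel_labels$emg,
              rec$channel_labels$eeg)
  write_edf(file.path(dir, "signals.edf"), sig, rec$rate_ecog, labels,
            physical_range = physical_range)
  kin <- data.frame(
    time_s = (seq_len(ncol(rec$kinematics)) - 1) / rec$rate_kin,
    vx = rec$kinematics[1, ], vy = rec$kinematics[2, ],
    vz = rec$kinematics[3, ])
  utils::write.table(kin, file.path(dir, "kinematics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rec$markers, file.path(dir, "markers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a session from a directory
#'
#' Expects the layout written by [save_session()]: `signals.edf` plus sidecar
#' `kinematics.tsv` and `markers.tsv`. Sample rates are read from the EDF
#' header and the kinematics time column; no resampling is performed.
#'
#' @param path Session directory.
#' @return A validated `session_recording`.
#' @export
load_session <- function(path) {
  for (f in c("signals.edf", "kinematics.tsv", "markers.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("session is missing required file: ", file.path(path, f))
  edf <- read_edf(file.path(path, "signals.edf"))
  is_ecog <- grepl("^ECOG", edf$labels)
  is_emg <- grepl("^EMG", edf$labels)
  is_eeg <- grepl("^EEG", edf$labels)
  if (!any(is_ecog)) stop("no ECOG* channels found in EDF")
  if (!any(is_emg)) stop("no EMG* channels found in EDF")
  kin <- utils::read.delim(file.path(path, "kinematics.tsv"))
  if (!all(c("time_s", "vx", "vy", "vz") %in% names(kin)))
    stop("kinematics.tsv must have columns time_s, vx, vy, vz")
  rate_kin <- round(1 / stats::median(diff(kin$time_s)))
  markers <- utils::read.delim(file.path(path, "markers.tsv"),
                               colClasses = c("numeric", "character",
                                              "character"))
  session_recording(
    ecog = edf$signals[is_ecog, , drop = FALSE],
    emg = edf$signals[is_emg, , drop = FALSE],
    eeg = if (any(is_eeg)) edf$signals[is_eeg, , drop = FALSE],
    kinematics = t(as.matrix(kin[, c("vx", "vy", "vz")])),
    rate_ecog = edf$rate, rate_kin = rate_kin, markers = markers,
    channel_labels = list(ecog = edf$labels[is_ecog],
                          emg = edf$labels[is_emg],
                          eeg = if (any(is_eeg)) edf$labels[is_eeg]))
}

#' Epoch a session into movement-aligned trials
#'
#' Each trial spans the half-open window `[onset - pre, onset + post)`.
#' Sample 1 of a trial maps to parent sample
#' `round((onset - pre) * rate) + 1` in every channel group at its own rate.
#' Onsets whose window does not fit inside the recording are dropped with a
#' warning.
#'
#' @param rec A `session_recording`.
#' @param onsets Movement onset times in seconds (EMG-defined).
#' @param pre Seconds before onset (default 4).
#' @param post Seconds after onset (default 8).
#' @return A `trial_set` data.frame: one row per retained trial with columns
#'   `onset_time`, `direction` (from the closest preceding GO marker, if any),
#'   `start_ecog`, `start_kin` (1-based parent indices), `rejected`,
#'   `reject_reason`; attributes `pre`, `post`, `n_ecog`, `n_kin`.
#' @export
extract_trials <- function(rec, onsets, pre = 4, post = 8) {
  dur <- session_duration(rec)
  onsets <- sort(onsets)
  keep <- onsets - pre >= 0 & onsets + post <= dur
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: window outside recording")
  onsets <- onsets[keep]
  go <- rec$markers[rec$markers$kind == "GO", , drop = FALSE]
  # a trial takes the direction of a GO cue at most `max_go_gap` s before it
  max_go_gap <- 2
  direction <- vapply(onsets, function(t0) {
    prev <- go$time_s[go$time_s <= t0 & go$time_s >= t0 - max_go_gap]
    if (length(prev) == 0) return("NONE")
    go$direction[go$time_s == max(prev)][1]
  }, "")
  trials <- data.frame(
    onset_time = onsets,
    direction = direction,
    start_ecog = round((onsets - pre) * rec$rate_ecog) + 1L,
    start_kin = round((onsets - pre) * rec$rate_kin) + 1L,
    rejected = rep(FALSE, length(onsets)),
    reject_reason = rep("", length(onsets)),
    stringsAsFactors = FALSE)
  structure(trials, pre = pre, post = post,
            n_ecog = round((pre + post) * rec$rate_ecog),
            n_kin = round((pre + post) * rec$rate_kin),
            class = c("trial_set", "data.frame"))
}

# Extract one trial's samples for a channel group ("ecog", "emg", "eeg") or a
# single labelled channel.
trial_signal <- function(rec, trials, i, what = "ecog") {
  n <- attr(trials, "n_ecog")
  i0 <- trials$start_ecog[i]
  if (what %in% c("ecog", "emg", "eeg")) {
    rec[[what]][, i0:(i0 + n - 1), drop = FALSE]
  } else {
    get_channel(rec, what)[i0:(i0 + n - 1)]
  }
}

trial_kinematics <- function(rec, trials, i) {
  n <- attr(trials, "n_kin")
  i0 <- trials$start_kin[i]
  rec$kinematics[, i0:(i0 + n - 1), drop = FALSE]
}

#' Reject trials contaminated by eye blinks
#'
#' Automated surrogate for visual inspection of the frontal EEG channels: a
#' trial is rejected when the absolute frontal-EEG amplitude inside its window
#' exceeds `z_thresh` robust standard deviations (median absolute deviation
#' scaled for normality) of the session-wide frontal amplitude. The rejected
#' set is monotone in `z_thresh`.
#'
#' @param trials A `trial_set`.
#' @param rec The parent `session_recording`.
#' @param z_thresh Positive rejection threshold (default 5).
#' @return The `trial_set` with `rejected`/`reject_reason` updated.
#' @export
reject_blink_trials <- function(trials, rec, z_thresh = 5) {
  stopifnot(z_thresh > 0)
  labs <- rec$channel_labels$eeg
  frontal <- labs[grepl("FP1|FZ", toupper(labs))]
  if (is.null(rec$eeg) || length(frontal) == 0) {
    warning("no frontal EEG channels; blink rejection skipped")
    return(trials)
  }
  chans <- lapply(frontal, function(l) {
    x <- get_channel(rec, l)
    x <- x - stats::median(x)
    list(x = abs(x), sd = stats::mad(x))
  })
  n <- attr(trials, "n_ecog")
  for (i in seq_len(nrow(trials))) {
    i0 <- trials$start_ecog[i]
    z <- max(vapply(chans, function(ch)
      max(ch$x[i0:(i0 + n - 1)]) / ch$sd, 0))
    if (z > z_thresh) {
      trials$rejected[i] <- TRUE
      trials$reject_reason[i] <- sprintf("blink (z = %.1f)", z)
    }
  }
  trials
}

#' Non-rejected subset of a trial set
#'
#' @param trials A `trial_set`.
#' @return The non-rejected trials with epoching attributes preserved.
#' @export
active_trials <- function(trials) {
  out <- trials[!trials$rejected, , drop = FALSE]
  attributes(out)[c("pre", "post", "n_ecog", "n_kin")] <-
    attributes(trials)[c("pre", "post", "n_ecog", "n_kin")]
  class(out) <- class(trials)
  out
}
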
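# Shared fixtures: small simulated sessions, cached per test run.

.session_cache <- new.env(parent = emptyenv())

# Small preset session (4 trials/direction unless overridden), cached by its
# argument signature.
cached_session <- function(preset = 1, seed = 7, n = 4, ...) {
  key <- paste(preset, seed, n, deparse(list(...)), collapse = "_")
  if (is.null(.session_cache[[key]])) {
    cfg <- sim_preset(preset, seed = seed, n_trials_per_direction = n, ...)
    .session_cache[[key]] <- simulate_session(cfg)
  }
  .session_cache[[key]]
}

# Selection bands straight from a sim config (4-Hz bands at the configured
# centers).
cfg_bands <- function(cfg) {
  list(gamma = band_spec(cfg$gamma_band$center, 4, "GAMMA_ERS"),
       alphabeta = band_spec(cfg$alphabeta_band$center, 4, "ALPHABETA_ERD"))
}

# Decoding frame (features at ECoG rate, kinematics clock, EMG-truth gate).
decoding_frame <- function(sim, gate_pad = 0.2, raw_only = FALSE) {
  rec <- sim$recording
  cfg <- sim$truth$config
  bands <- cfg_bands(cfg)
  emg <- reachdec:::emg_pipeline(rec)
  trials <- extract_trials(rec, emg$onsets)
  trials <- reachdec:::match_trials_to_bursts(trials, emg)
  fx <- if (raw_only) {
    structure(list(E = rec$ecog, rate = rec$rate_ecog,
                   times = (seq_len(ncol(rec$ecog)) - 1) / rec$rate_ecog,
                   bands = bands),
              class = "feature_series")
  } else {
    build_features(rec, bands$alphabeta, bands$gamma, resample = FALSE)
  }
  kt <- (seq_len(ncol(rec$kinematics)) - 1) / rec$rate_kin
  gate <- rep(FALSE, length(kt))
  for (j in seq_along(emg$onsets))
    gate[kt >= emg$onsets[j] - gate_pad & kt <= emg$offsets[j] + gate_pad] <-
      TRUE
  list(fx = fx, k = rec$kinematics, gate = gate,
       trial_id = reachdec:::trial_id_vector(trials, kt),
       trials = trials, emg = emg, rec = rec, times = kt)
}

# Independent event-matching oracle (used to recount TP/FP/FN).
recount_events <- function(events, truth, tol = 0.5) {
  used_e <- rep(FALSE, length(events))
  tp <- 0
  for (t0 in truth) {
    d <- abs(events - t0)
    d[used_e] <- Inf
    if (length(d) && min(d) <= tol) {
      used_e[which.min(d)] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = sum(!used_e), fn = length(truth) - tp)
}
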
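# Seeded synthetic-session simulator with known ground truth.
#
# Signal model per ECoG channel: 1/f background + an alpha-beta narrowband
# component whose envelope drops during movement (ERD) + a gamma narrowband
# component whose envelope rises during movement (ERS) + a slow (< 2 Hz)
# component equal to the lag-delayed linear projection of the 3-D minimum-jerk
# velocity through the ground-truth encoding matrix. Each narrowband component
# is an amplitude-stable tone (slow phase drift) plus a Gaussian spectral
# "skirt" carrying the configured bandwidth; the tone/skirt/background power
# split is calibrated analytically so that the ERD/ERS percentages measured by
# the baseline-normalised spectrogram match the configured Table-style effect
# sizes. See the methods vignette for why an amplitude-stable in-band carrier
# is required to reproduce both the printed effect sizes and near-perfect
# window-level onset classification.

#' Minimum-jerk speed profile
#'
#' `v(t) = (distance/duration) * (30*tau^2 - 60*tau^3 + 30*tau^4)`,
#' `tau = t/duration`, sampled at `rate`. Endpoint speeds are zero and the
#' profile integrates to `distance` with peak `1.875 * distance/duration` at
#' `tau = 0.5`.
#'
#' @param distance Reach distance in cm (> 0).
#' @param duration Movement duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @return Numeric speed vector (cm/s) at times `0, 1/rate, ...` up to
#'   `duration`.
#' @export
min_jerk_velocity <- function(distance, duration, rate) {
  if (distance <= 0 || duration <= 0 || rate <= 0)
    stop("distance, duration and rate must all be positive")
  t <- seq(0, duration, by = 1 / rate)
  tau <- t / duration
  (distance / duration) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

# Unit reach-direction vectors (lateral, forward, vertical). Lap-to-chest
# reaches have nonzero components on all three axes.
DIRECTION_VECTORS <- rbind(
  RTL = c(-0.55, 0.60, 0.58),
  RTM = c(0.20, 0.68, 0.70),
  RTR = c(0.60, 0.55, 0.58))
DIRECTION_VECTORS <- DIRECTION_VECTORS / sqrt(rowSums(DIRECTION_VECTORS^2))

# Default ground-truth encoding pattern: 8 channels x 3 axes, O(1) entries,
# full column rank, deterministic.
default_encoding_pattern <- function(n_ch = 8) {
  g <- outer(seq_len(n_ch), 1:3,
             function(c, a) sin(1.7 * c + 2.3 * a) + 0.5 * cos(0.9 * c * a))
  sweep(g, 2, sqrt(colSums(g^2) / n_ch), "/")  # rows ~ unit scale
}

#' Simulator configuration
#'
#' Defaults state the emulated protocol: three reach targets, 40 trials per
#' direction, randomized 6-8 s rest, 1-3 s movement durations, 30-40 cm
#' reaches, a 100-ms cortico-kinematic lag, and per-band spectral effect
#' sizes. See [sim_preset()] for participant-matched effect sizes.
#'
#' @param n_trials_per_direction Trials per reach direction (default 40).
#' @param directions Subset of `c("RTL", "RTM", "RTR")`.
#' @param rest_range Rest duration range in seconds (default `c(6, 8)`).
#' @param move_duration Per-trial movement duration range (default `c(1, 3)`).
#' @param reach_distance Reach distance range in cm (default `c(30, 40)`).
#' @param reaction_time GO-to-EMG-onset reaction time range in seconds.
#' @param gamma_band List `(center, width, ers_pct)`: Hz, Hz, percent.
#' @param alphabeta_band List `(center, width, erd_pct)`.
#' @param slow_gain Scale of the encoding matrix in uV per (cm/s); the
#'   ground-truth matrix is `slow_gain * default_encoding_pattern()`.
#' @param lag_true Cortico-kinematic lag in seconds (default 0.100).
#' @param noise_1f_scale Background 1/f noise standard deviation in uV.
#' @param emg_snr Burst-to-baseline EMG amplitude ratio.
#' @param kin_noise Kinematic observation noise as a fraction of each axis's
#'   RMS velocity amplitude over movement samples (default 0.10).
#' @param band_jitter Per-trial standard deviation (s) of the narrowband
#'   modulation edge times relative to the EMG-defined movement window
#'   (trial-to-trial variability of movement-related band activity),
#'   truncated at +/- 0.25 s so band onsets stay within the event-matching
#'   tolerance of the EMG onsets.
#' @param neural_ramp Gaussian transition scale (s, one sd) of the narrowband
#'   movement modulation (slow enough to confine AM sidebands near the line).
#' @param tone_rel,skirt_rel Measured-PSD ratio of the narrowband tone and
#'   skirt to the background at the band center (generator shape constants).
#' @param blink_trials Indices of trials receiving a frontal-EEG blink
#'   artifact.
#' @param direction_specific_encoding If `TRUE`, each direction uses its own
#'   (mutually orthogonalised) encoding matrix instead of a shared one.
#' @param rate_ecog,rate_kin Sampling rates in Hz.
#' @param n_ecog Number of ECoG channels (default 8).
#' @param seed Integer RNG seed; the simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trials_per_direction = 40,
                       directions = c("RTL", "RTM", "RTR"),
                       rest_range = c(6, 8),
                       move_duration = c(1, 3),
                       reach_distance = c(30, 40),
                       reaction_time = c(0.2, 0.5),
                       gamma_band = list(center = 155, width = 19,
                                         ers_pct = 281),
                       alphabeta_band = list(center = 22, width = 10,
                                             erd_pct = 87),
                       slow_gain = 3,
                       lag_true = 0.100,
                       noise_1f_scale = 10,
                       emg_snr = 9,
                       kin_noise = 0.10,
                       neural_ramp = 0.2,
                       band_jitter = 0.15,
                       tone_rel = 300,
                       skirt_rel = 0.25,
                       blink_trials = integer(0),
                       direction_specific_encoding = FALSE,
                       rate_ecog = 1200, rate_kin = 40, n_ecog = 8,
                       seed = 1) {
  cfg <- as.list(environment())
  nyq <- rate_ecog / 2
  for (b in list(gamma_band, alphabeta_band)) {
    if (b$center - b$width / 2 <= 0 || b$center + b$width / 2 >= nyq)
      stop("band (", b$center, " +/- ", b$width / 2,
           " Hz) must lie inside (0, Nyquist = ", nyq, " Hz)")
  }
  if (lag_true < 0) stop("lag_true must be >= 0")
  if (noise_1f_scale <= 0 || emg_snr <= 0) stop("scales must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Participant presets
#'
#' Effect-size presets matching the three recorded participants: alpha-beta
#' peak/ERD/bandwidth and gamma peak/ERS/bandwidth of
#' (22 Hz, 87\%, 10 Hz; 155 Hz, 281\%, 19 Hz),
#' (24 Hz, 54\%, 20 Hz; 64 Hz, 247\%, 8 Hz) and
#' (22 Hz, 52\%, 22 Hz; 77 Hz, 114\%, 14 Hz) respectively.
#'
#' @param participant 1, 2 or 3.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(participant, ...) {
  tab <- list(
    list(ab = list(center = 22, width = 10, erd_pct = 87),
         g = list(center = 155, width = 19, ers_pct = 281)),
    list(ab = list(center = 24, width = 20, erd_pct = 54),
         g = list(center = 64, width = 8, ers_pct = 247)),
    list(ab = list(center = 22, width = 22, erd_pct = 52),
         g = list(center = 77, width = 14, ers_pct = 114)))
  if (!(length(participant) == 1 && participant %in% 1:3))
    stop("participant must be 1, 2 or 3")
  p <- tab[[participant]]
  args <- list(gamma_band = p$g, alphabeta_band = p$ab)
  dots <- list(...)
  args[names(dots)] <- dots  # explicit overrides win
  do.call(sim_config, args)
}

# --- spectral building blocks ------------------------------------------------

# Background 1/f PSD (uV^2/Hz): flat below 0.5 Hz, 1/f up to 500 Hz, zero
# outside the amplifier band [0.1, 500] Hz. Normalised to total variance
# scale^2.
bg_psd <- function(f, scale) {
  norm <- 0.4 / 0.5 + log(500 / 0.5)  # integral of the unnormalised shape
  s <- ifelse(f >= 0.1 & f <= 500, 1 / pmax(f, 0.5), 0)
  s * scale^2 / norm
}

# Gaussian skirt PSD with peak value `peak` at `center` and FWHM `width`.
skirt_psd <- function(f, center, width, peak) {
  sigma <- width / (2 * sqrt(2 * log(2)))
  peak * exp(-(f - center)^2 / (2 * sigma^2))
}

# Realisation of a zero-mean Gaussian process with one-sided PSD psd_fun,
# length n at rate fs. Frequency-domain synthesis with complex-normal
# coefficients.
shaped_noise <- function(n, fs, psd_fun) {
  m <- stats::nextn(n, c(2, 3))
  f <- (1:(m / 2 - 1)) * fs / m
  s <- psd_fun(f)
  mag <- sqrt(s * fs * m / 2)
  coef <- mag * (stats::rnorm(length(f)) + 1i * stats::rnorm(length(f))) /
    sqrt(2)
  x_f <- complex(length.out = m)
  x_f[2:(m / 2)] <- coef
  x_f[(m / 2 + 2):m] <- Conj(rev(coef))
  Re(stats::fft(x_f, inverse = TRUE) / m)[1:n]
}

# Amplitude-stable tone: unit-amplitude cosine at f0 with random-walk phase
# (linewidth ~ sigma_step^2 * fs / (2*pi), kept well under 1 Hz).
drifting_tone <- function(n, fs, f0, sigma_step = 0.01) {
  phase <- 2 * pi * f0 * (0:(n - 1)) / fs +
    cumsum(stats::rnorm(n, sd = sigma_step)) + stats::runif(1, 0, 2 * pi)
  cos(phase)
}

# Coherent gain of the ERD/ERS spectrogram estimator for a pure tone:
# measured PSD value = (a^2/4) * (sum w)^2 / (fs * sum w^2).
tone_psd_gain <- function(fs, window_s = 0.5) {
  nw <- round(window_s * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  sum(w)^2 / (fs * sum(w^2))
}

# Gaussian smoothing by FFT convolution (circular edge effects negligible for
# kernels far shorter than the signal).
gaussian_smooth <- function(x, rate, sigma) {
  n <- length(x)
  m <- stats::nextn(n + round(8 * sigma * rate), c(2, 3))
  t <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / rate
  kern <- exp(-t^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  y <- Re(stats::fft(stats::fft(c(x, rep(x[n], m - n))) * stats::fft(kern),
                     inverse = TRUE) / m)
  y[1:n]
}

# Smooth 0/1 movement indicator sampled at `rate`; raised-cosine ramps lie
# inside [onset, offset] so no modulation precedes the nominal onset.
movement_indicator <- function(n, rate, onsets, offsets, ramp = 0.05) {
  env <- numeric(n)
  nr <- max(2L, round(ramp * rate))
  up <- (1 - cos(pi * seq(0, 1, length.out = nr))) / 2
  for (i in seq_along(onsets)) {
    i0 <- max(1L, round(onsets[i] * rate) + 1L)
    i1 <- min(n, round(offsets[i] * rate) + 1L)
    if (i1 - i0 + 1 < 2 * nr) next
    env[i0:i1] <- 1
    env[i0:(i0 + nr - 1)] <- up
    env[(i1 - nr + 1):i1] <- rev(up)
  }
  env
}

# Deterministic per-channel source gains for a shared narrowband cortical
# source; mixed signs emulate contacts on opposite sides of the generator.
# `phase` decorrelates the gamma and alpha-beta patterns.
source_gains <- function(n_ch, phase = 0.5) cos(1.1 * (0:(n_ch - 1)) + phase) + 0.3

# Noise-free 3-D velocity (cm/s) at `rate`, evaluated at times t + lead.
velocity_profile <- function(trials, rate, n, lead = 0) {
  v <- matrix(0, 3, n)
  t_grid <- (0:(n - 1)) / rate + lead
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset[i]; du <- trials$duration[i]
    j <- which(t_grid >= on & t_grid <= on + du)
    if (length(j) == 0) next
    tau <- (t_grid[j] - on) / du
    sp <- (trials$distance[i] / du) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
    u <- DIRECTION_VECTORS[trials$direction[i], ]
    v[, j] <- v[, j] + outer(u, sp)
  }
  v
}

# Squared Hamming-window leakage of the spectrogram kernel at `delta` Hz
# (relative to the coherent peak), for a `window_s` window at rate fs.
kernel_leakage <- function(fs, delta, window_s = 0.5) {
  nw <- round(window_s * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  t <- (0:(nw - 1)) / fs
  Mod(sum(w * exp(-2i * pi * delta * t)))^2 / sum(w)^2
}

# One narrowband component: amplitude-stable modulated tone + modulated
# Gaussian skirt + two unmodulated satellite lines at +/- sat_offset whose
# power equals the kernel leakage floor of the main line there. Without the
# satellites, every bin within the kernel mainlobe of a dominant line
# inherits the line's percent change, leaving the ERD/ERS peak a noise-driven
# plateau; the satellites pin the maximum to the configured center.
narrowband_component <- function(n, fs, center, width, tone_amp, skirt_peak,
                                 env, sat_offset = 3) {
  x <- tone_amp * drifting_tone(n, fs, center)
  if (skirt_peak > 0)
    x <- x + shaped_noise(n, fs, function(f)
      skirt_psd(f, center, width, skirt_peak))
  x <- x * env
  sat_amp <- tone_amp * sqrt(3 * kernel_leakage(fs, sat_offset))
  x + sat_amp * (drifting_tone(n, fs, center - sat_offset) +
                   drifting_tone(n, fs, center + sat_offset))
}

#' Simulate a recording session
#'
#' Deterministic given `cfg$seed`. Returns the session plus full ground truth
#' (onsets, offsets, directions, encoding matrix, lag, noise-free velocity and
#' the analytically expected ERD/ERS percentages implied by the calibration).
#'
#' Narrowband envelopes lead the EMG-defined movement window by `lag_true`
#' (cortical activity precedes the motor periphery), and the slow component of
#' channel `c` is `sum_a beta_true[c, a] * v_a(t + lag_true)`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_session` with elements `recording`
#'   (a [session_recording()]) and `truth`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$rate_ecog
  n_dir <- length(cfg$directions)
  n_tr <- cfg$n_trials_per_direction * n_dir
  dirs <- sample(rep(cfg$directions, cfg$n_trials_per_direction))
  rest <- stats::runif(n_tr, cfg$rest_range[1], cfg$rest_range[2])
  rt <- stats::runif(n_tr, cfg$reaction_time[1], cfg$reaction_time[2])
  dur <- stats::runif(n_tr, cfg$move_duration[1], cfg$move_duration[2])
  dist <- stats::runif(n_tr, cfg$reach_distance[1], cfg$reach_distance[2])
  go <- onset <- offset <- numeric(n_tr)
  t_cur <- 0
  for (i in seq_len(n_tr)) {
    go[i] <- t_cur + rest[i]
    onset[i] <- go[i] + rt[i]
    offset[i] <- onset[i] + dur[i]
    t_cur <- offset[i]
  }
  total_s <- ceiling(offset[n_tr] + 8.5)
  n <- total_s * fs
  nk <- total_s * cfg$rate_kin

  trials <- data.frame(onset = onset, offset = offset, duration = dur,
                       distance = dist, direction = dirs, go = go,
                       stringsAsFactors = FALSE)

  # Calibration in measured-PSD units at each band center, referenced to the
  # bipolar detection pair ECOG1 - ECOG0: the shared source appears there
  # with unit gain while the independent backgrounds add (PSD x 2), so the
  # spectrogram-measured percent change on the bipolar trace hits the
  # configured effect size.
  gain <- tone_psd_gain(fs)
  calib <- function(band, ers) {
    s_bg <- 2 * bg_psd(band$center, cfg$noise_1f_scale)
    tone_meas <- cfg$tone_rel * s_bg
    skirt_peak <- cfg$skirt_rel * s_bg
    k_mod <- cfg$tone_rel + cfg$skirt_rel
    pct <- if (ers) band$ers_pct else -band$erd_pct
    mult_sq <- 1 + (pct / 100) * (1 + k_mod) / k_mod
    if (mult_sq < 0)
      stop("configured ERD exceeds what the modulated power fraction allows")
    list(tone_amp = 2 * sqrt(tone_meas / gain), skirt_peak = skirt_peak,
         mult = sqrt(mult_sq),
         expected_pct = (mult_sq - 1) * k_mod / (1 + k_mod) * 100)
  }
  cal_g <- calib(cfg$gamma_band, ers = TRUE)
  cal_ab <- calib(cfg$alphabeta_band, ers = FALSE)

  # movement envelopes (cortical lead = lag_true)
  # Neural modulation: per-trial jittered movement window (band activity
  # does not track EMG exactly), box smoothed by a Gaussian
  # (sd = neural_ramp); spectrally compact transitions keep AM sidebands
  # below the stationary line leakage so the ERD/ERS peak stays at the
  # configured center.
  jit <- function() pmax(pmin(stats::rnorm(n_tr, sd = cfg$band_jitter),
                              0.25), -0.25)
  on_n <- onset - cfg$lag_true + jit()
  off_n <- offset - cfg$lag_true + jit()
  off_n <- pmax(off_n, on_n + 0.5)
  move_ecog <- gaussian_smooth(
    movement_indicator(n, fs, on_n, off_n, ramp = 2 / fs),
    fs, cfg$neural_ramp)
  env_g <- 1 + (cal_g$mult - 1) * move_ecog
  env_ab <- 1 + (cal_ab$mult - 1) * move_ecog

  # ground-truth encoding and slow component drive
  beta_true <- cfg$slow_gain * default_encoding_pattern(cfg$n_ecog)
  beta_dir <- NULL
  v_lead <- velocity_profile(trials, fs, n, lead = cfg$lag_true)
  if (cfg$direction_specific_encoding) {
    beta_dir <- lapply(seq_len(n_dir), function(k) {
      rot <- diag(cfg$n_ecog)[c(seq(k, cfg$n_ecog), seq_len(k - 1)), ]
      sgn <- (-1)^(seq_len(cfg$n_ecog) + k)
      cfg$slow_gain * (rot %*% default_encoding_pattern(cfg$n_ecog)) * sgn
    })
    names(beta_dir) <- cfg$directions
    slow <- matrix(0, cfg$n_ecog, n)
    for (d in cfg$directions) {
      vd <- velocity_profile(trials[trials$direction == d, , drop = FALSE],
                             fs, n, lead = cfg$lag_true)
      slow <- slow + beta_dir[[d]] %*% vd
    }
  } else {
    slow <- beta_true %*% v_lead
  }

  # Shared narrowband sources, scaled so the bipolar pair sees unit gain.
  y_g <- narrowband_component(n, fs, cfg$gamma_band$center,
                              cfg$gamma_band$width, cal_g$tone_amp,
                              cal_g$skirt_peak, env_g)
  y_ab <- narrowband_component(n, fs, cfg$alphabeta_band$center,
                               cfg$alphabeta_band$width, cal_ab$tone_amp,
                               cal_ab$skirt_peak, env_ab)
  g_gamma <- source_gains(cfg$n_ecog, 0.5)
  g_ab <- source_gains(cfg$n_ecog, 2.0)
  g_gamma <- g_gamma / (g_gamma[2] - g_gamma[1])
  g_ab <- g_ab / (g_ab[2] - g_ab[1])
  ecog <- matrix(0, cfg$n_ecog, n)
  for (c_i in seq_len(cfg$n_ecog)) {
    ecog[c_i, ] <- shaped_noise(n, fs,
                                function(f) bg_psd(f, cfg$noise_1f_scale)) +
      g_gamma[c_i] * y_g + g_ab[c_i] * y_ab + slow[c_i, ]
  }

  # EMG: baseline noise, burst amplitude (1 + emg_snr) x baseline; the
  # 150-ms rise time is a physiological EMG envelope ramp and keeps the
  # 3-SD threshold crossing close to the nominal onset
  move_emg <- movement_indicator(n, fs, onset, offset, ramp = 0.15)
  emg_base <- 5
  emg <- matrix(stats::rnorm(n, sd = emg_base) *
                  (1 + cfg$emg_snr * move_emg), 1, n)

  # EEG: background noise plus blink transients on configured trials
  eeg <- rbind(
    shaped_noise(n, fs, function(f) bg_psd(f, cfg$noise_1f_scale)),
    shaped_noise(n, fs, function(f) bg_psd(f, cfg$noise_1f_scale)))
  if (length(cfg$blink_trials) > 0) {
    nb <- round(0.4 * fs)
    blink <- 150 * (1 - cos(2 * pi * (0:(nb - 1)) / (nb - 1))) / 2
    for (i in cfg$blink_trials) {
      i0 <- round((onset[i] + 0.5) * fs)
      idx <- i0:(i0 + nb - 1)
      eeg[, idx] <- sweep(eeg[, idx, drop = FALSE], 2, blink, "+")
    }
  }

  # kinematics: noise-free velocity at 40 Hz plus additive white observation
  # noise at kin_noise x the per-axis RMS amplitude over movement samples
  # (one noise scale per axis for the whole session, like a real sensor)
  v_kin <- velocity_profile(trials, cfg$rate_kin, nk, lead = 0)
  moving <- colSums(v_kin^2) > 0
  amp <- sqrt(rowMeans(v_kin[, moving, drop = FALSE]^2))
  kin <- v_kin + matrix(stats::rnorm(3 * nk), 3, nk) * (cfg$kin_noise * amp)

  markers <- data.frame(
    time_s = c(go, onset, offset),
    kind = rep(c("GO", "EMG_ONSET", "EMG_OFFSET"), each = n_tr),
    direction = rep(dirs, 3),
    stringsAsFactors = FALSE)

  rec <- session_recording(
    ecog = ecog, emg = emg, eeg = eeg, kinematics = kin,
    rate_ecog = fs, rate_kin = cfg$rate_kin, markers = markers,
    channel_labels = list(ecog = paste0("ECOG", seq_len(cfg$n_ecog) - 1),
                          emg = "EMG_BICEPS",
                          eeg = c("EEG_FP1", "EEG_FZ")))
  trials$band_onset <- on_n; trials$band_offset <- off_n
  truth <- list(trials = trials, beta_true = beta_true, beta_dir = beta_dir,
                lag_true = cfg$lag_true, velocity = v_kin,
                gamma_mult = cal_g$mult, alphabeta_mult = cal_ab$mult,
                expected_ers_pct = cal_g$expected_pct,
                expected_erd_pct = cal_ab$expected_pct,
                gamma_tone_amp = cal_g$tone_amp,
                blink_trials = cfg$blink_trials, config = cfg)
  structure(list(recording = rec, truth = truth), class = "sim_session")
}

#' Save a simulated session with its ground truth
#'
#' Writes the [save_session()] layout plus `ground_truth.json`.
#'
#' @param sim A `sim_session`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_sim_session <- function(sim, dir) {
  save_session(sim$recording, dir)
  tr <- sim$truth
  gt <- list(trials = tr$trials, beta_true = tr$beta_true,
             lag_true = tr$lag_true,
             expected_ers_pct = tr$expected_ers_pct,
             expected_erd_pct = tr$expected_erd_pct,
             blink_trials = tr$blink_trials)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
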
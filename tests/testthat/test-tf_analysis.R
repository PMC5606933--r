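# Spectrogram, ERD/ERS normalisation, KS maps, band selection, bandwidth
# curves.

test_that("spectrogram localises tones and scales quadratically", {
  fs <- 1200
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  m <- spectrogram(x, fs)
  expect_equal(m$freqs, 0:600)
  expect_equal(diff(m$times)[1], 0.01, tolerance = 1e-9)
  expect_true(all(apply(m$power, 2, which.max) == 21))  # 20 Hz row
  m2 <- spectrogram(2 * x, fs)
  expect_equal(m2$power[21, ], 4 * m$power[21, ], tolerance = 1e-9)
  expect_error(spectrogram(x[1:100], fs), "window")
})

test_that("spectrogram columns match a brute-force windowed periodogram", {
  fs <- 1200
  set.seed(11)
  x <- rnorm(2 * fs)
  m <- spectrogram(x, fs)
  nw <- 600
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  for (j in c(1, 57, 141)) {
    start <- (j - 1) * 12 + 1
    seg <- x[start:(start + nw - 1)] * w
    # direct DFT at each 1-Hz bin
    ref <- vapply(0:600, function(f) {
      ph <- exp(-2i * pi * f * (0:(nw - 1)) / fs)
      p <- Mod(sum(seg * ph))^2 / (fs * sum(w^2))
      if (f %in% c(0, 600)) p else 2 * p
    }, 0)
    expect_equal(m$power[, j], ref, tolerance = 1e-10)
  }
})

test_that("windowed energy is conserved across bins (Parseval)", {
  fs <- 1200
  set.seed(12)
  x <- rnorm(2 * fs)
  m <- spectrogram(x, fs)
  nw <- 600
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  for (j in c(1, 40, 100)) {
    seg <- x[((j - 1) * 12 + 1):((j - 1) * 12 + nw)] * w
    direct <- sum(seg^2) / sum(w^2)  # Hamming-corrected windowed energy
    expect_lt(abs(sum(m$power[, j]) * 1 - direct) / direct, 0.05)
  }
})

make_flat_maps <- function(n_trials = 6, scale = 1, move_mult = 1,
                           seed = 1) {
  # synthetic aligned maps: constant expected power per frequency, optional
  # movement-interval multiplier
  set.seed(seed)
  freqs <- 0:50
  times <- seq(-4, 7.99, by = 0.01)
  lapply(seq_len(n_trials), function(i) {
    p <- matrix(rexp(length(freqs) * length(times)), length(freqs)) * scale
    p[, times >= 0 & times <= 2] <- p[, times >= 0 & times <= 2] * move_mult
    structure(list(power = p, freqs = freqs, times = times, window = 0.5),
              class = "tf_map")
  })
}

test_that("erders normalisation identities hold", {
  maps <- make_flat_maps(move_mult = 1)
  em <- erders(maps)
  bcols <- em$times >= -2 & em$times < -1.5
  # baseline columns average exactly to zero
  expect_equal(max(abs(rowMeans(em$pct_change[, bcols]))), 0,
               tolerance = 1e-9)
  # P = 2 x baseline during movement -> +100% there
  maps2 <- make_flat_maps(move_mult = 2, n_trials = 40)
  em2 <- erders(maps2)
  mcols <- em2$times >= 0.5 & em2$times <= 1.5
  expect_equal(mean(em2$pct_change[, mcols]), 100, tolerance = 10)
  expect_error(erders(maps[1]), "2 trials")
  # zero baseline power errors with the offending bin named
  maps3 <- make_flat_maps()
  for (i in seq_along(maps3)) maps3[[i]]$power[3, ] <- 0
  expect_error(erders(maps3), "zero baseline.*2 Hz")
  # per-trial baseline option gives the same zero-identity
  em4 <- erders(maps, per_trial = TRUE)
  expect_equal(max(abs(rowMeans(em4$pct_change[, bcols]))), 0,
               tolerance = 1e-9)
})

test_that("KS significance is calibrated on null data and detects real
           modulation", {
  null_maps <- make_flat_maps(n_trials = 40, seed = 3)
  ks <- ks_significance(null_maps, freq_range = c(5, 45),
                        time_range = c(0, 2), col_step = 40)
  expect_lt(mean(ks$p < 0.01), 0.03)
  expect_gt(median(ks$p), 0.1)
  mod_maps <- make_flat_maps(n_trials = 40, move_mult = 3, seed = 4)
  ks2 <- ks_significance(mod_maps, freq_range = c(10, 12),
                         time_range = c(0.5, 1), col_step = 25)
  expect_lt(max(ks2$p), 0.01)
  expect_error(ks_significance(null_maps[1]), "2 trials")
})

test_that("select_band is scale-invariant, errors on null maps, and
           recovers a constructed half-max extent", {
  sim <- cached_session(3, seed = 7, n = 4)
  rec <- sim$recording
  emg <- reachdec:::emg_pipeline(rec)
  trials <- extract_trials(rec, emg$onsets)
  ch <- bipolar_derivation(rec)
  maps <- lapply(seq_len(nrow(trials)), function(i) {
    n <- attr(trials, "n_ecog")
    i0 <- trials$start_ecog[i]
    spectrogram(ch[i0:(i0 + n - 1)], 1200, fmax = 150, t0 = -4)
  })
  maps10 <- lapply(maps, function(m) {m$power <- 100 * m$power; m})
  b1 <- select_band(erders(maps), c(30, 150), "ERS")
  b2 <- select_band(erders(maps10), c(30, 150), "ERS")
  expect_equal(b1$center, b2$center)
  expect_equal(b1$peak_pct, b2$peak_pct, tolerance = 1e-9)
  expect_equal(b1$lo, b1$center - 2)
  expect_equal(b1$hi, b1$center + 2)

  # null simulation: no significant bin -> explicit error
  null_cfg <- sim_preset(1, seed = 8, n_trials_per_direction = 4,
                         gamma_band = list(center = 155, width = 19,
                                           ers_pct = 0),
                         slow_gain = 1e-6)
  nsim <- simulate_session(null_cfg)
  nemg <- reachdec:::emg_pipeline(nsim$recording)
  ntr <- extract_trials(nsim$recording, nemg$onsets)
  nch <- bipolar_derivation(nsim$recording)
  nmaps <- lapply(seq_len(nrow(ntr)), function(i) {
    n <- attr(ntr, "n_ecog")
    i0 <- ntr$start_ecog[i]
    spectrogram(nch[i0:(i0 + n - 1)], 1200, fmax = 250, t0 = -4)
  })
  ks <- ks_significance(nmaps, freq_range = c(120, 190),
                        time_range = c(0, 1), col_step = 20)
  expect_error(select_band(erders(nmaps), c(120, 190), "ERS",
                           p_values = ks),
               "no movement-responsive band")

  # skirt-only construction with a numerically computed expected half-max;
  # a high skirt/background contrast keeps the half-max crossing steep so
  # the extent is measurable at desk-scale trial counts
  wide_cfg <- sim_preset(3, seed = 9, n_trials_per_direction = 8,
                         gamma_band = list(center = 90, width = 6,
                                           ers_pct = 400),
                         tone_rel = 0, skirt_rel = 50)
  wsim <- simulate_session(wide_cfg)
  wemg <- reachdec:::emg_pipeline(wsim$recording)
  wtr <- extract_trials(wsim$recording, wemg$onsets)
  wch <- bipolar_derivation(wsim$recording)
  wmaps <- lapply(seq_len(nrow(wtr)), function(i) {
    n <- attr(wtr, "n_ecog")
    i0 <- wtr$start_ecog[i]
    spectrogram(wch[i0:(i0 + n - 1)], 1200, fmax = 150, t0 = -4)
  })
  wb <- select_band(erders(wmaps), c(60, 120), "ERS")
  # numeric oracle: pct(f) ~ (m^2-1) * S_sk(f) / (S_sk(f) + S_bg(f));
  # half-max extent solved on a fine grid from the generator's own shapes
  cfgw <- wsim$truth$config
  m2 <- wsim$truth$gamma_mult^2
  fgrid <- seq(60, 120, by = 0.01)
  ssk <- reachdec:::skirt_psd(fgrid, 90, 6,
                              cfgw$skirt_rel * 2 *
                                reachdec:::bg_psd(90, cfgw$noise_1f_scale))
  sbg <- 2 * reachdec:::bg_psd(fgrid, cfgw$noise_1f_scale)
  pct <- (m2 - 1) * ssk / (ssk + sbg)
  expected_width <- diff(range(fgrid[pct >= max(pct) / 2]))
  expect_lt(abs(diff(wb$halfmax_band) - expected_width), 2.5)
})

test_that("bandwidth ratio approaches 0 dB on a null signal and favours
           narrow bands on a preset session", {
  set.seed(5)
  fs <- 1200
  x <- rnorm(60 * fs)
  curve <- bandwidth_ratio_curve(x, fs, onsets = c(10, 25, 40), center = 77,
                                 widths = c(4, 40))
  expect_lt(abs(curve$ratio_db[2]), 1)
  sim <- cached_session(3, seed = 7, n = 4)
  emg <- reachdec:::emg_pipeline(sim$recording)
  cv <- bandwidth_ratio_curve(bipolar_derivation(sim$recording), fs,
                              emg$onsets, 77, widths = c(2, 60))
  expect_gt(cv$ratio_db[1], cv$ratio_db[2])
  expect_error(bandwidth_ratio_curve(x, fs, 10, 500, widths = c(300)),
               "Nyquist")
})
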
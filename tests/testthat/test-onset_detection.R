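# Band-power windows, LDA training, continuous detection, F1 scoring.

test_that("band-power windows follow analytic power levels", {
  fs <- 1200
  t <- (0:(10 * fs - 1)) / fs
  band <- band_spec(80, 8)
  zero <- band_power_windows(rep(0, length(t)), fs, band)
  expect_true(all(zero$power == 0))
  expect_equal(diff(zero$times)[1], 0.05, tolerance = 1e-9)
  x <- sin(2 * pi * 80 * t)
  bp <- band_power_windows(x, fs, band)
  core <- 20:(length(bp$times) - 20)
  expect_equal(mean(bp$power[1, core]), 0.5, tolerance = 0.02)
  bp2 <- band_power_windows(2 * x, fs, band)
  expect_equal(bp2$power[1, core], 4 * bp$power[1, core], tolerance = 1e-6)
  expect_error(band_power_windows(x, fs, band_spec(620, 10)), "Nyquist")
})

test_that("window labelling matches burst intervals and a counting oracle", {
  fs <- 1200
  feats <- band_power_windows(rnorm(30 * fs), fs, band_spec(80, 8))
  none <- label_windows(feats, list(onsets = numeric(0),
                                    offsets = numeric(0)))
  expect_true(all(none$labels == "REST"))
  lab <- label_windows(feats, list(onsets = 5, offsets = 7))
  expect_equal(lab$labels[which.min(abs(lab$times - 5.5))], "MOVE")
  expect_equal(lab$labels[which.min(abs(lab$times - 6.0))], "MOVE")
  expect_equal(lab$labels[which.min(abs(lab$times - 3.0))], "REST")
  # MOVE fraction equals burst time / covered time within one window
  expect_equal(mean(lab$labels == "MOVE"), 2 / (30 - 0.2),
               tolerance = 0.2 / 30 + 0.01)
})

test_that("LDA separates separable clusters and rejects one-class input", {
  set.seed(6)
  n <- 200
  feats <- structure(list(
    times = seq(0, by = 0.05, length.out = 2 * n),
    power = matrix(c(10^rnorm(n, 0, 0.1), 10^rnorm(n, 2, 0.1)), nrow = 1),
    labels = rep(c("REST", "MOVE"), each = n),
    window_s = 0.2, step_s = 0.05), class = "window_features")
  model <- train_onset_lda(feats)
  pred <- reachdec:::predict_windows(model, feats)
  expect_equal(reachdec:::window_f1(pred, feats$labels), 1)
  one_class <- feats
  one_class$labels <- rep("REST", 2 * n)
  expect_error(train_onset_lda(one_class), "single class")
  unlabelled <- feats
  unlabelled$labels <- NULL
  expect_error(train_onset_lda(unlabelled), "labelled")
})

test_that("chance-level F1 matches the analytic 2pq/(p+q) oracle", {
  set.seed(7)
  p <- 0.2
  n <- 20000
  labels <- ifelse(runif(n) < p, "MOVE", "REST")
  for (q in c(0.3, 1)) {
    pred <- runif(n) < q
    expect_equal(reachdec:::window_f1(pred, labels), 2 * p * q / (p + q),
                 tolerance = 0.03)
  }
  expect_equal(chance_f1(p), 2 * p / (1 + p))
})

test_that("detection is debounced, gated, latency-consistent and
           amplitude-scale invariant", {
  sim <- cached_session(1, seed = 7, n = 5)
  rec <- sim$recording
  gb <- cfg_bands(sim$truth$config)$gamma
  res <- detect_session_onsets(rec, gb, n_train = 5)
  expect_equal(res$report$fn, 0)
  expect_equal(res$report$fp, 0)
  # report f1 equals an independent recount
  emg <- res$emg
  det <- detect_onsets(res$model,
                       label_windows(band_power_windows(
                         bipolar_derivation(rec), 1200, gb), emg),
                       true_onsets = emg$onsets)
  cnt <- recount_events(det$events, emg$onsets)
  expect_equal(det$report$tp, unname(cnt["tp"]))
  expect_equal(det$report$f1,
               unname(f1_score(cnt["tp"], cnt["fp"], cnt["fn"])))
  # gate is zero on a rest-only stretch
  rest_feats <- reachdec:::windows_in_time(
    band_power_windows(bipolar_derivation(rec), 1200, gb), 0, 5)
  rest_det <- detect_onsets(res$model, rest_feats)
  expect_equal(nrow(rest_det$gate), 0)
  expect_length(rest_det$events, 0)
  # shifting the features +100 ms shifts detected onsets by +100 ms
  feats <- band_power_windows(bipolar_derivation(rec), 1200, gb)
  shifted <- feats
  shifted$times <- shifted$times + 0.1
  d0 <- detect_onsets(res$model, feats)
  d1 <- detect_onsets(res$model, shifted)
  expect_equal(d1$events, d0$events + 0.1, tolerance = 0.051)
  # global amplitude scaling + retraining leaves detection unchanged
  scaled <- rec
  scaled$ecog <- rec$ecog * 7
  res2 <- detect_session_onsets(scaled, gb, n_train = 5)
  expect_equal(res2$report$f1, res$report$f1)
  expect_equal(res2$gate, res$gate, tolerance = 0.06)
  expect_error(detect_onsets(structure(list(trained = FALSE),
                                       class = "onset_model"), feats),
               "not trained")
})

test_that("F1 follows the exact formula and its properties", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(5, 5, 5), 0.5)
  expect_equal(f1_score(8, 2, 1), 16 / 19)
  expect_error(f1_score(0, 0, 0), "undefined")
  expect_error(f1_score(-1, 0, 0), "non-negative")
  # monotone increasing in TP with FP, FN fixed
  f <- vapply(1:20, function(tp) f1_score(tp, 3, 2), 0)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
})
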
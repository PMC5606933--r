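# Envelopes, feature construction, gated lagged regression, delay search.

test_that("envelope follows analytic and constructed references", {
  fs <- 1200
  t <- (0:(10 * fs - 1)) / fs
  band <- band_spec(80, 8)
  core <- (2 * fs):(8 * fs)
  a <- 3
  e <- envelope(a * sin(2 * pi * 80 * t), fs, band)
  expect_equal(mean(e[core]), 2 * a / pi, tolerance = 0.05 * 2 * a / pi)
  # amplitude-modulated carrier: envelope tracks the modulator
  mod <- 1 + 0.5 * sin(2 * pi * 1 * t)
  e2 <- envelope(mod * sin(2 * pi * 80 * t), fs, band)
  expect_gt(cor(e2[core], mod[core]), 0.99)
  # out-of-band tone leaves nothing
  e3 <- envelope(sin(2 * pi * 30 * t), fs, band)
  expect_lt(mean(e3[core]), 0.01)
  expect_error(envelope(t, fs, band_spec(640, 10)), "Nyquist")
})

test_that("feature series has the 24-row contract", {
  sim <- cached_session(1, seed = 7, n = 4)
  bands <- cfg_bands(sim$truth$config)
  fx <- build_features(sim$recording, bands$alphabeta, bands$gamma)
  expect_equal(nrow(fx$E), 24)
  expect_equal(fx$rate, 40)
  expect_equal(ncol(fx$E), ncol(sim$recording$kinematics))
  # envelope rows are non-negative
  expect_true(all(fx$E[9:24, ] >= 0))
  zero <- sim$recording
  zero$ecog[] <- 0
  fz <- build_features(zero, bands$alphabeta, bands$gamma)
  expect_equal(max(abs(fz$E)), 0)
  seven <- sim$recording
  seven$ecog <- seven$ecog[1:7, ]
  seven$channel_labels$ecog <- seven$channel_labels$ecog[1:7]
  expect_error(build_features(seven, bands$alphabeta, bands$gamma),
               "8 ECoG channels")
})

# 40-Hz white-noise feature world where the lag taps are genuinely distinct:
# exact linear recovery is possible and an independent normal-equations
# solve serves as the OLS oracle.
make_linear_world <- function(n = 2000, nf = 24, order = 3, t0 = 0.1,
                              seed = 13, smooth = 1) {
  set.seed(seed)
  e <- matrix(rnorm(nf * n), nf, n)
  if (smooth > 1)  # temporally smooth features give smooth delay curves
    e <- t(apply(e, 1, function(r)
      as.numeric(stats::filter(r, rep(1 / smooth, smooth),
                               circular = TRUE))))
  fx <- structure(list(E = e, rate = 40,
                       times = (0:(n - 1)) / 40, bands = NULL),
                  class = "feature_series")
  beta <- array(rnorm(nf * order * 3, sd = 0.3), dim = c(nf, order, 3))
  b <- c(1, -2, 0.5)
  gate <- rep(FALSE, n)
  gate[round(0.1 * n):round(0.9 * n)] <- TRUE
  x <- reachdec:::lagged_design(fx$E, 40, which(gate), 40, t0, order)
  k <- matrix(0, 3, n)
  k[, gate] <- t(x %*% matrix(beta, ncol = 3)) + b
  list(fx = fx, k = k, gate = gate, beta = beta, b = b, t0 = t0,
       order = order, x = x)
}

test_that("noiseless coefficients are recovered exactly and predictions are
           gated", {
  w <- make_linear_world()
  m <- fit_decoder(w$fx, w$k, w$gate, t0 = w$t0, order = w$order)
  expect_lt(max(abs(m$beta - w$beta)), 1e-6)
  expect_lt(max(abs(m$b - w$b)), 1e-6)
  pred <- predict_decoder(m, w$fx, w$gate)
  expect_equal(pred[, w$gate], w$k[, w$gate], tolerance = 1e-6)
  for (a in 1:3) expect_equal(cor(pred[a, w$gate], w$k[a, w$gate]), 1,
                              tolerance = 1e-9)
  # outside the gate the prediction is exactly zero
  expect_true(all(predict_decoder(m, w$fx, rep(FALSE, 2000)) == 0))
  expect_true(all(pred[, !w$gate] == 0))
})

test_that("OLS matches a brute-force normal-equations solve", {
  w <- make_linear_world(n = 400, nf = 4, order = 2, seed = 14)
  noisy_k <- w$k + matrix(rnorm(length(w$k), sd = 0.5), nrow = 3)
  m <- fit_decoder(w$fx, noisy_k, w$gate, t0 = w$t0, order = w$order)
  xb <- cbind(1, w$x)
  yb <- t(noisy_k[, w$gate])
  ref <- solve(t(xb) %*% xb, t(xb) %*% yb)
  expect_equal(m$coef, ref, tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  w <- make_linear_world(n = 400, nf = 4, order = 2)
  dup <- w$fx
  dup$E[2, ] <- dup$E[1, ]  # duplicate channel
  expect_error(fit_decoder(dup, w$k, w$gate, t0 = w$t0, order = 2),
               "ridge")
  few <- w$gate & seq_along(w$gate) < 48  # fewer samples than parameters
  expect_error(fit_decoder(w$fx, w$k, few, t0 = w$t0, order = 2),
               "fewer gated samples")
  m <- fit_decoder(w$fx, w$k, w$gate, t0 = w$t0, order = 2)
  fx48 <- w$fx
  fx48$rate <- 48
  expect_error(predict_decoder(m, fx48, w$gate), "rate")
  # ridge rescues a duplicated design (kinematics generated from it)
  xd <- reachdec:::lagged_design(dup$E, 40, which(w$gate), 40, w$t0, 2)
  kd <- matrix(0, 3, length(w$gate))
  kd[, w$gate] <- t(xd %*% matrix(w$beta, ncol = 3)) + w$b
  mr <- fit_decoder(dup, kd, w$gate, t0 = w$t0, order = 2, ridge = 1e-6)
  expect_equal(predict_decoder(mr, dup, w$gate)[, w$gate], kd[, w$gate],
               tolerance = 1e-2)
})

test_that("delay search recovers the true lag with a unimodal curve on
           noiseless data", {
  w <- make_linear_world(n = 4000, nf = 6, order = 2, t0 = 0.125, seed = 15,
                         smooth = 9)
  tid <- rep(NA_integer_, 4000)
  tid[w$gate] <- rep(1:8, length.out = sum(w$gate))
  sd_ <- search_delay(w$fx, w$k, w$gate, tid,
                      grid = seq(0.05, 0.2, by = 0.025), order = 2)
  expect_equal(sd_$t0, 0.125)
  cv <- sd_$curve$mean_r
  pk <- which.max(cv)
  expect_true(all(diff(cv[1:pk]) > 0))
  expect_true(all(diff(cv[pk:length(cv)]) < 0))
  expect_error(search_delay(w$fx, w$k, w$gate, tid, grid = numeric(0)),
               "empty")
})

test_that("simulator lag is recovered within one grid step end to end", {
  # the dedicated acceptance run measures the 50-replicate recovery rate;
  # here two single sessions at the criterion's session size
  for (lag in c(0.10, 0.15)) {
    sim <- cached_session(1, seed = 50 + round(lag * 100), n = 48,
                          lag_true = lag, directions = "RTM")
    fr <- decoding_frame(sim, raw_only = TRUE)
    sd_ <- search_delay(fr$fx, fr$k, fr$gate, fr$trial_id)
    expect_lte(abs(sd_$t0 - lag), 0.0051)
  }
})

test_that("per-trial predictions are bell-shaped on preset sessions", {
  sim <- cached_session(1, seed = 7, n = 4)
  fr <- decoding_frame(sim)
  m <- fit_decoder(fr$fx, fr$k, fr$gate & !is.na(fr$trial_id), t0 = 0.1)
  pred <- predict_decoder(m, fr$fx, fr$gate & !is.na(fr$trial_id))
  speed <- sqrt(colSums(pred^2))
  tr <- fr$trials
  interior_max <- vapply(seq_len(nrow(tr)), function(i) {
    s <- speed[fr$times >= tr$onset_time[i] & fr$times <= tr$offset_time[i]]
    pk <- which.max(s)
    pk > 0.1 * length(s) && pk < 0.9 * length(s)
  }, TRUE)
  expect_gte(mean(interior_max), 0.9)
})
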
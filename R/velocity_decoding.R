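# Feature construction (24-row E(t)), gated lagged multiple linear
# regression, and cortico-kinematic delay search.
#
# Lag convention: the decoder uses `order` taps spaced at the feature-series
# sample interval. With features at the native ECoG rate (1200 Hz) the
# default order 6 spans 5 ms; anti-alias filtering commutes with lagging, so
# feature rows are low-pass filtered once and each (t0, u) tap is pure
# indexing before regression on the kinematics clock.

#' Band-limited amplitude envelope
#'
#' Zero-phase band-pass, full-wave rectification, then a zero-phase low-pass
#' (default cutoff 5 Hz). For an unmodulated in-band sinusoid of amplitude A
#' the output approaches the rectified-sine mean `2A/pi`.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param band A [band_spec()].
#' @param lp_cutoff Smoothing low-pass cutoff in Hz (default 5).
#' @return Non-negative envelope, same length as `x`.
#' @export
envelope <- function(x, rate, band, lp_cutoff = 5) {
  if (band$hi >= rate / 2) stop("band above Nyquist")
  xf <- bandpass_filtfilt(x, rate, band$lo, band$hi, order = 3)
  lowpass_filtfilt(abs(xf), rate, lp_cutoff, order = 4)
}

#' Build the 24-row decoder feature series
#'
#' Rows 1-8: raw unfiltered ECoG; rows 9-16: alpha-beta band envelopes;
#' rows 17-24: gamma band envelopes. With `resample = TRUE` (default) the
#' rows are anti-alias filtered and decimated to the kinematics rate.
#'
#' @param rec A `session_recording` with exactly 8 ECoG channels.
#' @param alphabeta,gamma [band_spec()]s for the envelope rows.
#' @param resample Resample to `rec$rate_kin` (default TRUE). With
#'   `FALSE` the series stays at the ECoG rate for lagged fitting.
#' @return A `feature_series`: `E` `[24 x n]`, `rate`, `times`, `bands`.
#' @export
build_features <- function(rec, alphabeta, gamma, resample = TRUE) {
  n_ch <- nrow(rec$ecog)
  if (n_ch != 8)
    stop("expected 8 ECoG channels (feature vector of length 24); got ",
         n_ch, " (would give ", 3 * n_ch, " rows)")
  fs <- rec$rate_ecog
  e <- rbind(
    rec$ecog,
    t(vapply(seq_len(n_ch), function(i)
      envelope(rec$ecog[i, ], fs, alphabeta), numeric(ncol(rec$ecog)))),
    t(vapply(seq_len(n_ch), function(i)
      envelope(rec$ecog[i, ], fs, gamma), numeric(ncol(rec$ecog)))))
  out <- structure(list(E = e, rate = fs,
                        times = (seq_len(ncol(e)) - 1) / fs,
                        bands = list(alphabeta = alphabeta, gamma = gamma)),
                   class = "feature_series")
  if (resample) out <- resample_features(out, rec$rate_kin)
  out
}

# Anti-alias filter (0.8 * target Nyquist) and decimate a feature series.
resample_features <- function(fx, rate_out) {
  if (fx$rate == rate_out) return(fx)
  dec <- fx$rate / rate_out
  if (abs(dec - round(dec)) > 1e-9)
    stop("feature rate must be an integer multiple of the target rate")
  cutoff <- 0.8 * rate_out / 2
  ef <- t(apply(fx$E, 1, lowpass_filtfilt, fs = fx$rate, cutoff = cutoff))
  idx <- seq(1, ncol(ef), by = dec)
  structure(list(E = ef[, idx, drop = FALSE], rate = rate_out,
                 times = fx$times[idx], bands = fx$bands),
            class = "feature_series")
}

# Low-pass the rows once for lag-tap sampling on the output clock (no-op if
# the feature rate already equals the output rate).
prepare_lag_rows <- function(fx, rate_out) {
  if (fx$rate == rate_out) return(fx$E)
  cutoff <- 0.8 * rate_out / 2
  t(apply(fx$E, 1, lowpass_filtfilt, fs = fx$rate, cutoff = cutoff))
}

# Lagged, gated design matrix on the output clock. `rows` are the prepared
# feature rows at fx_rate; output sample times are (k-1)/rate_out. Column
# block u (0-based) holds rows sampled at t - t0 - u/fx_rate.
lagged_design <- function(rows, fx_rate, out_idx, rate_out, t0, order) {
  nf <- nrow(rows)
  n <- length(out_idx)
  x <- matrix(0, n, nf * order)
  base <- round(((out_idx - 1) / rate_out - t0) * fx_rate) + 1
  for (u in 0:(order - 1)) {
    idx <- base - u
    if (any(idx < 1) || any(idx > ncol(rows)))
      stop("lagged samples fall outside the recording; shrink t0/order ",
           "or the gated range")
    x[, (u * nf + 1):((u + 1) * nf)] <- t(rows[, idx, drop = FALSE])
  }
  x
}

# Minimum-norm least squares via SVD pseudo-inverse (rcond = 1e-10).
#
# After anti-alias filtering, lag taps spaced at the ECoG sample interval are
# linearly dependent to near machine precision when sampled on the 40-Hz
# kinematics clock, so the full lagged design is structurally near-singular;
# the minimum-norm solution over that subspace is the appropriate plain-OLS
# reading. Genuine rank deficiency (duplicate/constant channels, too few
# samples) is caught by the caller on the single-tap design.
ols_solve <- function(x, y, ridge = 0) {
  if (ridge > 0) {
    xtx <- crossprod(x) + diag(ridge, ncol(x))
    return(list(coef = solve(xtx, crossprod(x, y)), rank = ncol(x)))
  }
  sv <- svd(x)
  keep <- sv$d > 1e-10 * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  list(coef = sv$v %*% (dinv * crossprod(sv$u, y)), rank = sum(keep))
}

#' Fit the gated, lagged multiple linear regression decoder
#'
#' Ordinary least squares of the 3-D velocity on the concatenated lagged,
#' gated features: `K(t) = b + sum_u h(t-u) E(t-u) beta(u) + eta(t)`,
#' restricted to output samples where the gate is open. The output is
#' defined as zero where the gate is closed (rest velocity is truly zero),
#' so `b` absorbs only gated-interval structure.
#'
#' @param fx A `feature_series` (any rate that is an integer multiple of the
#'   kinematics rate; lags are taken at the feature rate).
#' @param k Kinematics matrix `[3 x n]` at `rate_out`.
#' @param gate Logical vector of length `n` (the Heaviside `h(t)` sampled on
#'   the kinematics clock).
#' @param t0 Cortico-kinematic delay in seconds (default 0.100).
#' @param order Number of lag taps (default 6; 5 ms at 1200 Hz).
#' @param rate_out Kinematics rate in Hz (default 40).
#' @param ridge Optional ridge penalty (default 0 = plain least squares).
#' @param prepared Optional pre-filtered rows from `prepare_lag_rows()`
#'   (used internally to avoid refiltering across a delay grid).
#' @return A `decoder_model`: `b` (3-vector), `beta` `[order x 24 x 3]`,
#'   `t0`, `order`, `residual_var` (per axis), plus fitting metadata.
#' @export
fit_decoder <- function(fx, k, gate, t0 = 0.1, order = 6, rate_out = 40,
                        ridge = 0, prepared = NULL) {
  stopifnot(inherits(fx, "feature_series"))
  if (order < 1) stop("order must be >= 1")
  if (t0 < 0) stop("t0 must be >= 0")
  rows <- if (is.null(prepared)) prepare_lag_rows(fx, rate_out) else prepared
  sel <- which(gate)
  nf <- nrow(fx$E)
  p <- nf * order + 1
  if (length(sel) < p)
    stop("fewer gated samples (", length(sel), ") than parameters (", p, ")")
  x <- cbind(1, lagged_design(rows, fx$rate, sel, rate_out, t0, order))
  y <- t(k[, sel, drop = FALSE])
  if (ridge == 0) {
    # identifiability check on the single-tap design: lag taps are allowed
    # to be collinear (see ols_solve), channels are not
    x0 <- x[, 1:(nf + 1), drop = FALSE]
    d0 <- svd(x0, nu = 0, nv = 0)$d
    if (sum(d0 > max(dim(x0)) * .Machine$double.eps * d0[1]) < nf + 1)
      stop("rank-deficient design (collinear or constant feature rows); ",
           "consider the ridge option")
  }
  fit <- ols_solve(x, y, ridge)
  resid <- y - x %*% fit$coef
  structure(list(b = fit$coef[1, ],
                 beta = array(fit$coef[-1, ], dim = c(nf, order, 3)),
                 coef = fit$coef, t0 = t0, order = order,
                 feature_rate = fx$rate, rate_out = rate_out,
                 ridge = ridge,
                 residual_var = colMeans(resid^2),
                 n_gated = length(sel)),
            class = "decoder_model")
}

#' Predict gated 3-D velocity
#'
#' Evaluates the fitted model where the gate is open and returns exactly
#' zero elsewhere.
#'
#' @param model A `decoder_model`.
#' @param fx The `feature_series` (same rate as used in fitting).
#' @param gate Logical vector on the kinematics clock.
#' @param prepared Optional pre-filtered rows.
#' @return Matrix `[3 x length(gate)]` of predicted velocity (cm/s).
#' @export
predict_decoder <- function(model, fx, gate, prepared = NULL) {
  if (fx$rate != model$feature_rate)
    stop("feature rate (", fx$rate, ") differs from training rate (",
         model$feature_rate, ")")
  rows <- if (is.null(prepared)) prepare_lag_rows(fx, model$rate_out)
          else prepared
  khat <- matrix(0, 3, length(gate))
  sel <- which(gate)
  if (length(sel) == 0) return(khat)
  x <- cbind(1, lagged_design(rows, fx$rate, sel, model$rate_out, model$t0,
                              model$order))
  khat[, sel] <- t(x %*% model$coef)
  khat
}

# Pearson correlation with a zero-variance guard (returns 0 with a warning).
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("degenerate (constant) series in correlation; r set to 0")
    return(0)
  }
  stats::cor(a, b)
}

# Per-trial leave-one-out correlations at a fixed delay, computed by Gram
# matrix downdates (fit once, subtract each trial's contribution).
# mode "axes": mean per-axis r; mode "speed": r of Euclidean speed.
loo_correlations <- function(rows, fx_rate, k, gate, trial_id, t0, order,
                             rate_out, mode = "axes") {
  sel <- which(gate & !is.na(trial_id))
  ids <- trial_id[sel]
  x <- cbind(1, lagged_design(rows, fx_rate, sel, rate_out, t0, order))
  y <- t(k[, sel, drop = FALSE])
  xtx <- crossprod(x)
  xty <- crossprod(x, y)
  lam <- max(diag(xtx)) * 1e-10  # tiny Tikhonov guard for collinear taps
  reg <- diag(lam, ncol(x))
  un <- unique(ids)
  r <- rep(NA_real_, length(un))
  for (j in seq_along(un)) {
    ti <- ids == un[j]
    xi <- x[ti, , drop = FALSE]
    yi <- y[ti, , drop = FALSE]
    coef <- tryCatch(
      solve(xtx - crossprod(xi) + reg, xty - crossprod(xi, yi)),
      error = function(e) NULL)
    if (is.null(coef)) next
    pred <- xi %*% coef
    r[j] <- if (mode == "speed") {
      safe_cor(sqrt(rowSums(pred^2)), sqrt(rowSums(yi^2)))
    } else {
      mean(vapply(1:3, function(a) safe_cor(pred[, a], yi[, a]), 0))
    }
  }
  data.frame(trial = un, r = r)
}

#' Search the cortico-kinematic delay
#'
#' For each candidate delay, computes the leave-one-trial-out mean Pearson
#' correlation and returns the delay with the highest mean (ties toward the
#' smallest delay). The default grid starts below the physiological 100-ms
#' anchor so smaller simulated lags remain recoverable, in 5-ms steps.
#'
#' The search model defaults to a single lag tap (`order = 1`): with the full
#' collinear 6-tap block the objective is nearly flat in the delay (the block
#' can re-time itself internally) and its maximum sits at the block center
#' rather than the physiological delay. The full decoder order is applied
#' when fitting at the chosen delay.
#'
#' @param fx A `feature_series`.
#' @param k Kinematics `[3 x n]`.
#' @param gate Logical gate on the kinematics clock.
#' @param trial_id Integer trial id per kinematics sample (NA outside
#'   trials); defines the leave-one-out folds.
#' @param grid Candidate delays in seconds (default 0.050-0.200 by 0.005).
#' @param order Lag taps of the search model (default 1; see Details).
#' @param rate_out Kinematics rate (default 40).
#' @param mode Correlation mode, `"axes"` or `"speed"`.
#' @return List: `t0` (best delay), `curve` (data.frame `t0`, `mean_r`).
#' @export
search_delay <- function(fx, k, gate, trial_id,
                         grid = seq(0.05, 0.2, by = 0.005), order = 1,
                         rate_out = 40, mode = "axes") {
  if (length(grid) == 0) stop("empty delay grid")
  rows <- prepare_lag_rows(fx, rate_out)
  mean_r <- vapply(grid, function(t0) {
    r <- loo_correlations(rows, fx$rate, k, gate, trial_id, t0, order,
                          rate_out, mode)$r
    mean(r, na.rm = TRUE)
  }, 0)
  best <- which(mean_r == max(mean_r))[1]
  list(t0 = grid[best], curve = data.frame(t0 = grid, mean_r = mean_r))
}
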
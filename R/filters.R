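# IIR filter design and zero-phase filtering.
#
# The pre-installed stack has no DSP package, so Butterworth design (analog
# prototype -> frequency transform -> bilinear transform) and filtfilt are
# implemented here on top of stats::filter, which runs the recursion in C.

# Polynomial with given roots, leading coefficient 1 (complex arithmetic).
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth filter design
#'
#' Designs digital Butterworth low-, high- or band-pass filters via the
#' bilinear transform, returning transfer-function coefficients.
#'
#' @param n Filter order (for `"pass"` the returned filter has order `2n`,
#'   as is conventional: `n` analog prototype poles are mapped to `2n`).
#' @param cutoff Cutoff frequency in Hz (length 1 for `"low"`/`"high"`,
#'   length 2 `c(lo, hi)` for `"pass"`).
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, cutoff, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (n < 1) stop("filter order must be >= 1")
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("cutoff frequencies must lie inside (0, fs/2); got ",
         paste(signif(cutoff, 6), collapse = ", "), " at fs = ", fs)
  # analog Butterworth prototype poles (radius 1, left half plane)
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff)
    p <- wc * pa
    z <- complex(0)
    gain <- wc^n
  } else if (type == "high") {
    wc <- warp(cutoff)
    p <- wc / pa
    z <- rep(0 + 0i, n)
    gain <- 1
  } else {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2])
      stop("band-pass requires cutoff = c(lo, hi) with lo < hi")
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    half <- pa * bw / 2
    disc <- sqrt(half^2 - w0^2)
    p <- c(half + disc, half - disc)
    z <- rep(0 + 0i, n)
    gain <- bw^n
  }
  # bilinear transform s -> 2fs (z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Frequency response of a digital filter
#'
#' @param filt List with `b`, `a` coefficients (as from [butter_design()]).
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response at each frequency.
#' @export
filter_response <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  ev <- function(cf, w) {
    m <- length(cf)
    sapply(w, function(wi) sum(cf * exp(-1i * wi * (0:(m - 1)))))
  }
  ev(filt$b, w) / ev(filt$a, w)
}

# Single-pass IIR filtering y = filter(b, a, x) using stats::filter (C code).
filter_ba <- function(filt, x) {
  b <- filt$b; a <- filt$a
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) == 1) return(v / a[1])
  as.numeric(stats::filter(v / a[1], -a[-1] / a[1], method = "recursive"))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection edge padding,
#' yielding zero phase distortion and a squared magnitude response.
#'
#' @param filt List with `b`, `a` coefficients.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  n <- length(x)
  ord <- max(length(filt$a), length(filt$b)) - 1
  npad <- min(n - 1, max(3 * ord, 300))
  if (npad < 1) stop("signal too short to filter")
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xx <- c(pre, x, post)
  y <- filter_ba(filt, xx)
  y <- rev(filter_ba(filt, rev(y)))
  y[(npad + 1):(npad + n)]
}

# Zero-phase Butterworth band-pass helper used throughout the package.
bandpass_filtfilt <- function(x, fs, lo, hi, order = 3) {
  filtfilt(butter_design(order, c(lo, hi), fs, "pass"), x)
}

# Zero-phase Butterworth low-pass helper.
lowpass_filtfilt <- function(x, fs, cutoff, order = 4) {
  filtfilt(butter_design(order, cutoff, fs, "low"), x)
}
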
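# Minimal EDF (European Data Format) writer/reader.
#
# Implements the subset of EDF needed to carry multichannel electrophysiology:
# ASCII header (256 bytes + 256 per channel), 1-second data records, 16-bit
# little-endian samples, linear physical/digital scaling per channel. No
# pre-installed package provides EDF, hence this purpose-built implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write signals to an EDF file
#'
#' @param path Output file path.
#' @param signals Numeric matrix `[n_channels x n_samples]`.
#' @param rate Sampling rate in Hz (samples per 1-second data record); must be
#'   an integer and `n_samples` must be a whole multiple of it.
#' @param labels Character vector of channel labels.
#' @param physical_range Either `NULL` (per-channel symmetric range from the
#'   data) or a 2-column matrix of `c(min, max)` rows per channel. Using
#'   `c(-32768, 32767)` makes integer-valued signals round-trip bit-exactly.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, rate, labels,
                      physical_range = NULL) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  ns <- nrow(signals)
  n <- ncol(signals)
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  if (n %% rate != 0)
    stop("signal length must be a whole number of 1-second records")
  nrec <- n %/% rate
  if (length(labels) != ns) stop("need one label per channel")
  if (is.null(physical_range)) {
    physical_range <- t(apply(signals, 1, function(x) {
      m <- max(abs(x), 1e-6)
      c(-m, m)
    }))
  }
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 8))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(labels, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(formatC(physical_range[, 1], format = "g", digits = 7), 8),
    field(formatC(physical_range[, 2], format = "g", digits = 7), 8),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),
    field(rep(rate, ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  # digital conversion
  pmin <- physical_range[, 1]; pmax <- physical_range[, 2]
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- matrix(0L, ns, n)
  for (c_i in seq_len(ns)) {
    d <- round((signals[c_i, ] - pmin[c_i]) * scale[c_i] + dmin)
    dig[c_i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  # records: for each second, each channel's block
  idx <- matrix(seq_len(n), nrow = rate)  # column r = record r sample indices
  out <- integer(ns * n)
  pos <- 0L
  for (r in seq_len(nrec)) {
    block <- t(dig[, idx[, r], drop = FALSE])  # rate x ns
    out[(pos + 1):(pos + rate * ns)] <- as.integer(block)
    pos <- pos + rate * ns
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` matrix `[n_channels x n_samples]`, `rate`,
#'   `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(8))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (hdr_bytes != 256 * (ns + 1)) stop("corrupt EDF header in ", path)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel rates in one EDF are not supported")
  rate <- spr[1] / rec_dur
  n <- nrec * spr[1]
  raw <- readBin(con, integer(), n = ns * n, size = 2, endian = "little",
                 signed = TRUE)
  signals <- matrix(0, ns, n)
  scale <- (pmax - pmin) / (dmax - dmin)
  per_rec <- ns * spr[1]
  for (r in seq_len(nrec)) {
    block <- matrix(raw[((r - 1) * per_rec + 1):(r * per_rec)], nrow = spr[1])
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    signals[, cols] <- t(block)
  }
  signals <- (signals - dmin) * scale + pmin
  list(signals = signals, rate = rate, labels = labels)
}
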
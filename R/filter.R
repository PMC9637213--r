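# Zero-phase least-squares FIR band-pass filtering --------------------------

#' Least-squares linear-phase FIR design (type I)
#'
#' Designs an odd-length symmetric FIR filter whose amplitude response is the
#' weighted least-squares fit to a piecewise-linear desired response over a
#' set of frequency bands; the gaps between bands are "don't care" regions.
#' This is the classic firls design used for EEG band-pass filtering.
#'
#' @param n_taps odd filter length.
#' @param bands numeric matrix with one row per band: `f_lo`, `f_hi` (Hz).
#' @param gains matrix of the same shape: desired amplitude at each band edge.
#' @param fs sampling rate (Hz).
#' @param weights per-band weights (default 1).
#' @return numeric vector of `n_taps` coefficients.
#' @export
firls <- function(n_taps, bands, gains, fs, weights = rep(1, nrow(bands))) {
  stopifnot(n_taps %% 2 == 1, nrow(bands) == nrow(gains))
  if (any(bands < 0) || any(bands > fs / 2) || any(bands[, 2] <= bands[, 1])) {
    stop("band edges must be increasing and inside [0, fs/2]", call. = FALSE)
  }
  M <- (n_taps - 1L) %/% 2L
  # normalized frequency F in cycles/sample; A(F) = sum_k a_k cos(2 pi k F)
  F1 <- bands[, 1] / fs
  F2 <- bands[, 2] / fs
  # I(m) = integral of cos(2 pi m F) over each band, summed with weights,
  # for m = 0 .. 2M (needed for Q_{kl} = (I(k+l) + I(|k-l|)) / 2)
  m <- 0:(2L * M)
  Ivec <- numeric(length(m))
  for (b in seq_along(F1)) {
    w <- weights[b]
    Ivec[1] <- Ivec[1] + w * (F2[b] - F1[b])
    mm <- m[-1]
    Ivec[-1] <- Ivec[-1] +
      w * (sin(2 * pi * mm * F2[b]) - sin(2 * pi * mm * F1[b])) / (2 * pi * mm)
  }
  k <- 0:M
  Q <- matrix(0.5 * (Ivec[outer(k, k, `+`) + 1L] + Ivec[abs(outer(k, k, `-`)) + 1L]),
              M + 1L, M + 1L)
  # b_k = sum_bands w * integral of D(F) cos(2 pi k F) dF, D linear per band
  bvec <- numeric(M + 1L)
  for (b in seq_along(F1)) {
    w <- weights[b]
    g1 <- gains[b, 1]; g2 <- gains[b, 2]
    slope <- (g2 - g1) / (F2[b] - F1[b])
    c0 <- g1 - slope * F1[b]  # D(F) = c0 + slope * F
    # k = 0 term
    bvec[1] <- bvec[1] + w * (c0 * (F2[b] - F1[b]) +
                                slope * (F2[b]^2 - F1[b]^2) / 2)
    kk <- k[-1]
    s2 <- sin(2 * pi * kk * F2[b]); s1 <- sin(2 * pi * kk * F1[b])
    c2 <- cos(2 * pi * kk * F2[b]); c1 <- cos(2 * pi * kk * F1[b])
    int_cos <- (s2 - s1) / (2 * pi * kk)
    int_Fcos <- (F2[b] * s2 - F1[b] * s1) / (2 * pi * kk) +
      (c2 - c1) / (2 * pi * kk)^2
    bvec[-1] <- bvec[-1] + w * (c0 * int_cos + slope * int_Fcos)
  }
  a <- tryCatch(solve(Q, bvec), error = function(e) {
    # near-singular normal equations (long filters): minimum-norm LS solution
    sv <- svd(Q)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], bvec)) / sv$d[pos])
  })
  a <- as.numeric(a)
  c(rev(a[-1]) / 2, a[1], a[-1] / 2)
}

#' Amplitude response of a linear-phase FIR filter
#'
#' @param h coefficient vector (odd length, symmetric).
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return real amplitude response at `f` (can be negative in stop ripple).
#' @export
fir_response <- function(h, f, fs) {
  M <- (length(h) - 1L) %/% 2L
  a <- c(h[M + 1L], 2 * h[(M + 2L):length(h)])
  vapply(f, function(fi) sum(a * cos(2 * pi * (0:M) * fi / fs)), numeric(1))
}

#' Apply an FIR filter forward and backward (zero phase)
#'
#' Equivalent to filtering with `h`, time-reversing, filtering again and
#' reversing, with zero padding at the edges; implemented in one pass by
#' convolving with the autocorrelation of `h` (FFT-based).  Rows of `x` are
#' filtered independently.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param h FIR coefficients.
#' @return filtered data, same shape as `x`.
#' @export
fir_filtfilt <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nh <- length(h)
  if (n < 3L * nh) {
    stop(sprintf("record too short to filter: %d samples < 3 x %d filter taps",
                 n, nh), call. = FALSE)
  }
  g <- stats::convolve(h, h, type = "open")  # conv(h, rev(h)): zero-phase kernel
  nfft <- stats::nextn(n + 2L * nh - 2L, 2)
  G <- stats::fft(c(g, numeric(nfft - length(g))))
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(x[i, ], numeric(nfft - n)))
    full <- Re(stats::fft(X * G, inverse = TRUE)) / nfft
    out[i, ] <- full[nh:(nh + n - 1L)]
  }
  dimnames(out) <- dimnames(x)
  if (vec) out[1, ] else out
}

filter_cache <- new.env(parent = emptyenv())

#' Design (and cache) the default band-pass filter
#'
#' Pass band `[low, high]` with transitions of width `trans_low` / `trans_high`
#' centered on the edges; everything further out is a stop band.
#'
#' @param low,high band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param n_taps odd filter length; default 1651 at `fs = 500` (about 3.3 s),
#'   long enough for a meaningful 0.1 Hz edge.  Scaled proportionally for
#'   other sampling rates.
#' @param trans_low,trans_high transition band widths (Hz).
#' @return FIR coefficient vector.
#' @export
design_bandpass <- function(low, high, fs, n_taps = NULL,
                            trans_low = 0.05, trans_high = 2) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2", call. = FALSE)
  }
  if (is.null(n_taps)) {
    n_taps <- 2L * as.integer(round(1651 * fs / 500)) %/% 2L + 1L
  }
  key <- paste(low, high, fs, n_taps, trans_low, trans_high, sep = "|")
  if (!is.null(filter_cache[[key]])) return(filter_cache[[key]])
  stop_lo <- low - trans_low / 2
  pass_lo <- low + trans_low / 2
  pass_hi <- min(high - trans_high / 2, fs / 2)
  stop_hi <- min(high + trans_high / 2, fs / 2)
  if (pass_hi <= pass_lo) stop("band too narrow for transition widths", call. = FALSE)
  # the desired response covers the whole of [0, fs/2], with explicit linear
  # ramps across the transitions: leaving the transitions as "don't care"
  # regions lets the least-squares fit grow large spurious lobes there when
  # the filter is short relative to the transition width
  bands <- rbind(c(stop_lo, pass_lo), c(pass_lo, pass_hi))
  gains <- rbind(c(0, 1), c(1, 1))
  if (stop_lo > 0) {
    bands <- rbind(c(0, stop_lo), bands)
    gains <- rbind(c(0, 0), gains)
  }
  if (stop_hi < fs / 2) {
    bands <- rbind(bands, c(pass_hi, stop_hi), c(stop_hi, fs / 2))
    gains <- rbind(gains, c(1, 0), c(0, 0))
  }
  h <- firls(n_taps, bands, gains, fs)
  filter_cache[[key]] <- h
  h
}

#' Band-pass filter an EEG record
#'
#' Zero-phase (two-way) least-squares FIR band-pass, applied per channel.
#'
#' @param record an [eeg_record].
#' @param low_hz,high_hz pass-band edges (Hz); the analysis convention is a
#'   fixed 0.1 Hz low edge with `high_hz` in 4, 13, 20 or 30.
#' @param n_taps,trans_low,trans_high see [design_bandpass()].
#' @return the record with filtered data (a `band` field records the band).
#' @export
bandpass <- function(record, low_hz = 0.1, high_hz = 20, n_taps = NULL,
                     trans_low = 0.05, trans_high = 2) {
  stopifnot(inherits(record, "eeg_record"))
  h <- design_bandpass(low_hz, high_hz, record$fs, n_taps,
                       trans_low = trans_low, trans_high = trans_high)
  record$data <- fir_filtfilt(record$data, h)
  record$band <- c(low = low_hz, high = high_hz)
  record
}
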
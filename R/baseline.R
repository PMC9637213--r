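# Classical per-band baseline features --------------------------------------
#
# The comparison feature set: sample entropy, RMS, median frequency and peak
# frequency, computed per interval in each of the five canonical EEG bands
# and averaged over the intervals of a task.  With 60 channels this yields
# 4 x 5 x 3 x 60 = 3600 features per record.

#' Canonical EEG band scheme
#'
#' @param delta,theta,alpha,beta,gamma numeric `c(low, high)` pairs in Hz.
#'   Defaults: delta 0.1-4, theta 4-8, alpha 8-13, beta 13-30, gamma
#'   30-100 Hz (edges shared between adjacent bands).
#' @return named list of band edges, class `band_scheme`.
#' @export
band_scheme <- function(delta = c(0.1, 4), theta = c(4, 8), alpha = c(8, 13),
                        beta = c(13, 30), gamma = c(30, 100)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha,
                beta = beta, gamma = gamma)
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  stopifnot(all(lo < hi), all(lo[-1] >= hi[-length(hi)]))
  structure(bands, class = "band_scheme")
}

#' Root mean square
#'
#' @param x numeric series (length >= 1).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  sqrt(mean(x^2))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts pairs of m-length templates
#' within Chebyshev distance `r` (self-matches excluded) and `A` the same for
#' m+1-length templates.
#'
#' @param x numeric series, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy, or `NA` when no template matches exist (undefined).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  stopifnot(length(x) > m + 1L, r > 0)
  ab <- .sampen_counts(as.numeric(x), as.integer(m), r)
  if (ab[2] == 0 || ab[1] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

# One-sided Hann periodogram: data.frame(freq, power)
periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))  # periodic Hann
  X <- stats::fft(x * w)
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2
  data.frame(freq = (seq_len(half) - 1L) * fs / n, power = p)
}

#' Median frequency of the power spectrum
#'
#' Frequency splitting the cumulative one-sided Hann periodogram power in
#' half, with each bin's power treated as centered on its frequency
#' (midpoint-cumulative convention) and linear interpolation between bins.
#' A single spectral line on a bin returns that bin's frequency exactly;
#' two equal lines return their midpoint.
#'
#' @param x numeric series, length >= 8.
#' @param fs sampling rate (Hz).
#' @return frequency in Hz.
#' @export
median_frequency <- function(x, fs) {
  stopifnot(length(x) >= 8L)
  pg <- periodogram(x, fs)
  total <- sum(pg$power)
  if (total <= 0) stop("zero total power", call. = FALSE)
  # cumulative power with half of each bin's mass at its own frequency;
  # non-decreasing, so the inverse is well defined (plateaus -> mean)
  y <- cumsum(pg$power) - pg$power / 2
  # quantize so that float noise on an exact-half plateau (equal spectral
  # lines) does not pick an arbitrary end of the plateau
  tol <- 1e-9 * total
  yq <- round(y / tol) * tol
  stats::approx(yq, pg$freq, xout = round(total / 2 / tol) * tol,
                ties = mean, rule = 2)$y
}

#' Peak frequency of the power spectrum
#'
#' Frequency of the maximum-power periodogram bin; ties break to the lowest
#' frequency.
#'
#' @inheritParams median_frequency
#' @return frequency in Hz.
#' @export
peak_frequency <- function(x, fs) {
  stopifnot(length(x) >= 8L)
  pg <- periodogram(x, fs)
  if (sum(pg$power) <= 0) stop("zero total power", call. = FALSE)
  pg$freq[which.max(pg$power)]
}

# 1 Hz interior transitions so adjacent bands crossfade tightly and their
# powers add up to the broadband power
baseline_band_filter <- function(record, band) {
  lo <- band[1]; hi <- band[2]
  bandpass(record, lo, hi,
           trans_low = if (lo <= 0.5) 0.05 else 1, trans_high = 1)
}

#' Classical baseline feature table
#'
#' Per record: every combination of feature type (sampen, rms, medfreq,
#' peakfreq) x band x task x channel, computed per interval and averaged over
#' the task's intervals.  Missing task epochs give `NA` columns with a
#' warning.
#'
#' @param records list of [eeg_record]s (unfiltered; band filtering happens
#'   here per band).
#' @param scheme a [band_scheme()].
#' @param tasks character vector of tasks (default all three).
#' @param spec an [interval_spec()] for the per-epoch analysis interval.
#' @param sampen_m,sampen_r_factor sample-entropy parameters (`r =
#'   r_factor * sd` per series).
#' @return data.frame: `record_id`, `group`, then one column per feature
#'   named `{feature}_{band}_{task}_{channel}`.
#' @export
baseline_feature_table <- function(records, scheme = band_scheme(),
                                   tasks = c("Standard", "Novelty", "Target"),
                                   spec = interval_spec(0, 500),
                                   sampen_m = 2L, sampen_r_factor = 0.2) {
  feats <- c("sampen", "rms", "medfreq", "peakfreq")
  one_interval <- function(x, fs) {
    r <- sampen_r_factor * stats::sd(x)
    c(sampen = if (r > 0) sample_entropy(x, sampen_m, r) else NA_real_,
      rms = rms(x),
      medfreq = median_frequency(x, fs),
      peakfreq = peak_frequency(x, fs))
  }
  rows <- lapply(records, function(rec) {
    labs <- rec$channel_labels
    vals <- list()
    for (bname in names(scheme)) {
      filtered <- baseline_band_filter(rec, scheme[[bname]])
      for (task in tasks) {
        ivs <- suppressWarnings(task_intervals(filtered, task, spec))
        cn <- paste0(rep(feats, length(labs)), "_", bname, "_", task, "_",
                     rep(labs, each = length(feats)))
        if (!length(ivs)) {
          warning("record ", rec$subject_id, " has no ", task,
                  " intervals; NA features", call. = FALSE)
          vals[[paste(bname, task)]] <-
            stats::setNames(rep(NA_real_, length(cn)), cn)
          next
        }
        per_iv <- lapply(ivs, function(iv) {
          as.vector(vapply(seq_along(labs), function(ci) {
            one_interval(iv[ci, ], rec$fs)
          }, numeric(length(feats))))
        })
        vals[[paste(bname, task)]] <-
          stats::setNames(Reduce(`+`, per_iv) / length(per_iv), cn)
      }
    }
    c(list(record_id = rec$subject_id, group = rec$group),
      as.list(unlist(unname(vals))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
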
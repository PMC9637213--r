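# Synthetic two-group EEG cohort --------------------------------------------
#
# Emulates the statistical structure the pipeline assumes: 60-channel
# recordings at 500 Hz with 1/f background noise mixed through a spatially
# smooth full-rank matrix, oddball event streams (Standard / Novelty /
# Target) with onset-locked ERP templates, and a planted group difference:
# the PD group carries a larger Standard-task ERP amplitude and an extra
# background source, both along one unit-norm spatial direction centered on
# an electrode (Fz by default).  That planted direction is the ground truth
# that parameter-recovery tests check CSP against.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# exp(-d^2 / (2 sd^2)) over grid Euclidean distance from `center`;
# channels off the grid get 0
gaussian_profile <- function(grid, labels, center, sd = 1.5) {
  cc <- grid_cell(grid, center)
  vapply(labels, function(l) {
    cell <- grid$label_to_cell[[l]]
    if (is.null(cell)) return(0)
    exp(-sum((cell - cc)^2) / (2 * sd^2))
  }, numeric(1))
}

#' Configuration of the synthetic cohort
#'
#' @param n_per_group subjects (= records) per group.
#' @param grid electrode grid; channel order is the grid's build order.
#' @param fs sampling rate (Hz).
#' @param duration_s record length (s).
#' @param events_per_task named counts for Standard/Novelty/Target; onsets
#'   keep a minimum inter-onset gap of 4 s and a full 4-s window inside the
#'   record.
#' @param erp_amplitude matrix groups x tasks (rows "control","pd"; columns
#'   task names) of peak ERP amplitudes (microvolts) at the profile center.
#' @param erp_center electrode at which the ERP (and the planted background
#'   source) peaks.
#' @param erp_shape onset-locked template shape: `"bump"` (default; unipolar
#'   half-sine, P3-like) or `"damped_cosine"` (10 Hz damped oscillation).
#' @param erp_profile_sd spatial spread of the ERP profile (grid cells).
#' @param amp_jitter_sd relative per-record amplitude jitter (lognormal sd).
#' @param noise_sigma background noise standard deviation per channel
#'   (microvolts).
#' @param noise_exponent 1/f spectral exponent (power ~ f^-a).
#' @param source_gain named (control, pd) amplitudes (microvolts) of the
#'   extra background source along the planted direction.
#' @param mixing channel mixing matrix (default: spatially smooth Gaussian
#'   kernel over the grid, rows unit norm); must be full rank.
#' @param snr scalar multiplier applied to all ERP amplitudes.
#' @param seed base seed; per-record seeds are derived from it.
#' @return object of class `synthetic_config` (includes the unit-norm
#'   planted direction `planted_direction`).
#' @export
synthetic_config <- function(n_per_group = 25L,
                             grid = default_layout_60(),
                             fs = 500,
                             duration_s = 60,
                             events_per_task = c(Standard = 10L, Novelty = 2L,
                                                 Target = 2L),
                             erp_amplitude = rbind(
                               control = c(Standard = 5, Novelty = 6, Target = 6),
                               pd = c(Standard = 10, Novelty = 6, Target = 6)),
                             erp_center = "Fz",
                             erp_shape = c("bump", "damped_cosine"),
                             erp_profile_sd = 1.5,
                             amp_jitter_sd = 0.1,
                             noise_sigma = 10,
                             noise_exponent = 1,
                             source_gain = c(control = 0, pd = 3),
                             mixing = NULL,
                             snr = 1,
                             seed = 1L) {
  labels <- names(grid$label_to_cell)
  n_ch <- length(labels)
  if (is.null(mixing)) {
    cells <- do.call(rbind, grid$label_to_cell)
    d2 <- as.matrix(stats::dist(cells))^2
    mixing <- exp(-d2 / (2 * 1.0^2))
    mixing <- mixing / sqrt(rowSums(mixing^2))  # unit row norm: var sigma^2/ch
  }
  stopifnot(nrow(mixing) == n_ch, ncol(mixing) == n_ch)
  if (qr(mixing)$rank < n_ch) stop("mixing matrix is rank deficient", call. = FALSE)
  v <- gaussian_profile(grid, labels, erp_center, erp_profile_sd)
  v <- v / sqrt(sum(v^2))
  n_events <- sum(events_per_task)
  if (4 + (n_events - 1) * 4 > duration_s) {
    stop("events cannot be scheduled: need ", 4 + (n_events - 1) * 4,
         " s, record is ", duration_s, " s", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group), grid = grid,
                 labels = labels, fs = fs, duration_s = duration_s,
                 events_per_task = events_per_task,
                 erp_amplitude = erp_amplitude, erp_center = erp_center,
                 erp_shape = match.arg(erp_shape),
                 erp_profile_sd = erp_profile_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 noise_sigma = noise_sigma, noise_exponent = noise_exponent,
                 source_gain = source_gain, mixing = mixing, snr = snr,
                 planted_direction = v, seed = as.integer(seed)),
            class = "synthetic_config")
}

# unit-variance 1/f-shaped noise, one column per series
pink_noise <- function(n, n_series, exponent) {
  white <- matrix(stats::rnorm(n * n_series), n, n_series)
  if (exponent == 0) return(white)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # FFT bin frequencies
  H <- c(0, f[-1]^(-exponent / 2))
  H <- H / sqrt(mean(H[-1]^2))  # preserve variance (DC removed)
  shaped <- Re(stats::mvfft(stats::mvfft(white) * H, inverse = TRUE)) / n
  # renormalize exactly to unit sample variance per series
  shaped <- sweep(shaped, 2, apply(shaped, 2, stats::sd), "/")
  shaped
}

# onset-locked ERP time course, 300 ms support, unit peak.
# "bump": unipolar half-sine deflection (P3-like slow positivity) -- carries
# both variance and mean amplitude, so log-variance and mask-mean features
# are informative.  "damped_cosine": 10 Hz damped oscillation; nearly zero
# mean, so mask-mean features see almost nothing of it.
erp_time_course <- function(fs, shape = c("bump", "damped_cosine"),
                            duration = 0.3, freq = 10, tau = 0.1) {
  shape <- match.arg(shape)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  switch(shape,
         bump = sin(pi * t / duration),
         damped_cosine = cos(2 * pi * freq * t) * exp(-t / tau))
}

schedule_events <- function(config) {
  n <- sum(config$events_per_task)
  slack <- config$duration_s - 4 - (n - 1) * 4
  s <- sort(stats::runif(n, 0, slack))
  onsets_s <- 2 + (seq_len(n) - 1) * 4 + s
  tasks <- sample(rep(names(config$events_per_task), config$events_per_task))
  data.frame(task = tasks,
             onset_sample = as.integer(round(onsets_s * config$fs)))
}

#' Generate one synthetic EEG record
#'
#' Mixed 1/f background noise plus the group's extra source plus the
#' group/task ERP template at each event onset; bit-reproducible for a given
#' `(config, group, subject_id, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param group `"control"` or `"pd"`.
#' @param subject_id identifier.
#' @param seed integer seed for this record.
#' @return an [eeg_record].
#' @export
generate_record <- function(config, group, subject_id, seed) {
  stopifnot(inherits(config, "synthetic_config"), group %in% c("control", "pd"))
  n <- as.integer(round(config$duration_s * config$fs))
  n_ch <- length(config$labels)
  with_seed(seed, {
    events <- schedule_events(config)
    data <- if (config$noise_sigma > 0) {
      config$noise_sigma *
        (config$mixing %*% t(pink_noise(n, n_ch, config$noise_exponent)))
    } else {
      matrix(0, n_ch, n)
    }
    gain <- config$source_gain[[group]]
    if (gain > 0) {
      src <- pink_noise(n, 1L, config$noise_exponent)[, 1]
      data <- data + gain * config$planted_direction %o% src
    }
    profile <- gaussian_profile(config$grid, config$labels, config$erp_center,
                                config$erp_profile_sd)
    tc <- erp_time_course(config$fs, config$erp_shape)
    for (i in seq_len(nrow(events))) {
      amp <- config$snr * config$erp_amplitude[group, events$task[i]]
      if (amp == 0) next
      if (config$amp_jitter_sd > 0) {
        amp <- amp * exp(stats::rnorm(1, 0, config$amp_jitter_sd))
      }
      i0 <- events$onset_sample[i]
      idx <- (i0 + 1L):min(i0 + length(tc), n)
      data[, idx] <- data[, idx] +
        amp * profile %o% tc[seq_along(idx)]
    }
    rownames(data) <- config$labels
    eeg_record(data, config$fs, events, group, subject_id)
  })
}

#' Generate a full labelled cohort
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (controls then PD) and `manifest`: a
#'   data.frame (`subject_id`, `group`, `seed`) plus attributes
#'   `planted_direction` and `erp_amplitude` recording the ground truth.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- rep(c("control", "pd"), each = config$n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 c(seq_len(config$n_per_group), seq_len(config$n_per_group)))
  seeds <- config$seed + seq_along(ids)
  records <- lapply(seq_along(ids), function(i) {
    generate_record(config, groups[i], ids[i], seeds[i])
  })
  manifest <- data.frame(subject_id = ids, group = groups, seed = seeds)
  attr(manifest, "planted_direction") <-
    stats::setNames(config$planted_direction, config$labels)
  attr(manifest, "erp_amplitude") <- config$erp_amplitude
  list(records = records, manifest = manifest)
}

#' Write a cohort to disk
#'
#' One native record pair per subject (see [write_record()]) plus
#' `manifest.json` with the ground truth.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records) {
    write_record(rec, file.path(dir, rec$subject_id))
  }
  m <- cohort$manifest
  jsonlite::write_json(
    list(subjects = m,
         planted_direction = as.list(attr(m, "planted_direction")),
         erp_amplitude = as.data.frame(attr(m, "erp_amplitude"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reference cohorts for parameter-recovery and null calibration
#'
#' `planted_cohort_config()` states the high-SNR recovery world: 25 + 25
#' subjects, 60 s records at 500 Hz, and two group differences along the
#' Fz-centered planted direction: a Standard-task ERP twice as large in the
#' PD group, and a PD-only background source of 10 microvolts against
#' 1 microvolt channel noise -- background noise at one tenth of the planted
#' source's standard deviation, the regime in which spatial-filter recovery
#' is expected to succeed.  Background noise here is spatially white
#' (identity mixing): under correlated noise only the spatial pattern, not
#' the filter, can align with the planted direction.  `null_cohort_config()` is the same world with
#' every group difference removed.
#'
#' @param seed base seed.
#' @return a [synthetic_config()].
#' @export
planted_cohort_config <- function(seed = 1L) {
  synthetic_config(
    n_per_group = 25L, duration_s = 60, fs = 500,
    erp_amplitude = rbind(control = c(Standard = 5, Novelty = 6, Target = 6),
                          pd = c(Standard = 10, Novelty = 6, Target = 6)),
    noise_sigma = 1, source_gain = c(control = 0, pd = 10),
    mixing = diag(60), seed = seed)
}

#' @rdname planted_cohort_config
#' @export
null_cohort_config <- function(seed = 1L) {
  synthetic_config(
    n_per_group = 25L, duration_s = 60, fs = 500,
    erp_amplitude = rbind(control = c(Standard = 5, Novelty = 6, Target = 6),
                          pd = c(Standard = 5, Novelty = 6, Target = 6)),
    noise_sigma = 1, source_gain = c(control = 0, pd = 0),
    mixing = diag(60), seed = seed)
}
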
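# Onset-centered epochs and analysis intervals ------------------------------

#' Interval specification within an epoch
#'
#' An analysis interval starts `start_ms` after the task onset and lasts
#' `length_ms`; the standard grid uses lengths of 250, 500 and 1000 ms.
#'
#' @param start_ms non-negative offset from the task onset (ms).
#' @param length_ms interval length (ms).
#' @return object of class `interval_spec`.
#' @export
interval_spec <- function(start_ms = 0, length_ms = 500) {
  stopifnot(start_ms >= 0, length_ms > 0)
  structure(list(start_ms = start_ms, length_ms = length_ms),
            class = "interval_spec")
}

#' Cut onset-centered epochs for one task
#'
#' Each epoch is `epoch_s` seconds long (2000 samples at 500 Hz) with the
#' task onset centered, i.e. at 0-based index `length/2`.  Events whose
#' window would run off either end of the record are skipped with a warning.
#'
#' @param record a (typically band-pass filtered) [eeg_record].
#' @param task one of "Standard", "Novelty", "Target".
#' @param epoch_s epoch length in seconds (default 4).
#' @return list of epochs; each has `data` (channels x samples), `task`,
#'   `onset_index` (0-based, = samples/2) and `onset_sample` in the record.
#' @export
epoch <- function(record, task, epoch_s = 4) {
  stopifnot(inherits(record, "eeg_record"))
  len <- as.integer(round(epoch_s * record$fs))
  half <- len %/% 2L
  onsets <- record$events$onset_sample[record$events$task == task]
  n <- ncol(record$data)
  usable <- onsets - half >= 0L & onsets + (len - half) <= n
  if (any(!usable)) {
    warning(sprintf("%d %s event(s) too close to the record edge were skipped",
                    sum(!usable), task), call. = FALSE)
  }
  if (!any(usable)) {
    warning("no usable ", task, " events in record ", record$subject_id,
            call. = FALSE)
    return(list())
  }
  lapply(onsets[usable], function(on) {
    structure(list(
      data = record$data[, (on - half + 1L):(on - half + len), drop = FALSE],
      task = task, onset_index = half, onset_sample = on,
      fs = record$fs), class = "eeg_epoch")
  })
}

#' Extract an analysis interval from an epoch
#'
#' Returns the half-open sample range
#' `[onset_index + start_ms*fs/1000, onset_index + (start_ms+length_ms)*fs/1000)`.
#'
#' @param ep an epoch from [epoch()].
#' @param spec an [interval_spec()].
#' @return channels-by-n numeric matrix.
#' @export
extract_interval <- function(ep, spec) {
  stopifnot(inherits(ep, "eeg_epoch"), inherits(spec, "interval_spec"))
  i0 <- ep$onset_index + as.integer(round(spec$start_ms * ep$fs / 1000))
  n <- as.integer(round(spec$length_ms * ep$fs / 1000))
  if (i0 + n > ncol(ep$data)) {
    stop(sprintf("interval [%g, %g] ms does not fit in a %d-sample epoch",
                 spec$start_ms, spec$start_ms + spec$length_ms, ncol(ep$data)),
         call. = FALSE)
  }
  ep$data[, (i0 + 1L):(i0 + n), drop = FALSE]
}

#' All analysis intervals of one task in a record
#'
#' Convenience wrapper: epochs the record and extracts the interval from each
#' usable event.
#'
#' @inheritParams epoch
#' @param spec an [interval_spec()].
#' @return list of channels-by-n matrices (possibly empty).
#' @export
task_intervals <- function(record, task, spec) {
  eps <- epoch(record, task)
  lapply(eps, extract_interval, spec = spec)
}
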
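# EEG record container and on-disk formats ----------------------------------

#' Construct an EEG record
#'
#' @param data channels-by-samples numeric matrix (microvolts); row names are
#'   the channel labels (or pass `channel_labels`).
#' @param fs sampling rate (Hz).
#' @param events data.frame with columns `task` (character: "Standard",
#'   "Novelty", "Target") and `onset_sample` (0-based integer sample index).
#' @param group `"control"` or `"pd"`.
#' @param subject_id identifier string.
#' @param channel_labels optional label vector overriding `rownames(data)`.
#' @return object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, events, group, subject_id,
                       channel_labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(channel_labels) || length(channel_labels) != nrow(data)) {
    stop("need one channel label per data row", call. = FALSE)
  }
  stopifnot(fs > 0, group %in% c("control", "pd"))
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(c("task", "onset_sample") %in% names(events)))
    events <- events[order(events$onset_sample), , drop = FALSE]
    if (any(diff(events$onset_sample) <= 0)) {
      stop("event onsets must be strictly increasing", call. = FALSE)
    }
  } else {
    events <- data.frame(task = character(), onset_sample = integer())
  }
  rownames(data) <- channel_labels
  structure(list(subject_id = as.character(subject_id), group = group,
                 channel_labels = channel_labels, fs = fs,
                 data = data, events = events),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s (%s): %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Write a record in the native format
#'
#' `<path>.dat`: raw little-endian float32, channel-major (all samples of
#' channel 1, then channel 2, ...).  `<path>.json`: sidecar with labels,
#' sampling rate, group, subject and events.
#'
#' @param record an [eeg_record].
#' @param path file stem (extensions are appended).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  side <- list(subject = record$subject_id, group = record$group,
               labels = record$channel_labels, fs = record$fs,
               n_samples = ncol(record$data),
               events = record$events)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(record$data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a record in the native format
#'
#' @param path file stem as given to [write_record()].
#' @return an [eeg_record].
#' @export
read_record <- function(path) {
  json_path <- paste0(path, ".json")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path, call. = FALSE)
  if (!file.exists(dat_path)) stop("missing data file: ", dat_path, call. = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  n_ch <- length(side$labels)
  n_values <- file.size(dat_path) / 4
  if (n_values != n_ch * side$n_samples) {
    stop(sprintf(
      "format error: sidecar declares %d channels x %d samples but %s holds %g values",
      n_ch, side$n_samples, dat_path, n_values), call. = FALSE)
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n_values, size = 4L, endian = "little")
  data <- matrix(v, nrow = n_ch, byrow = TRUE,
                 dimnames = list(side$labels, NULL))
  events <- if (length(side$events)) {
    data.frame(task = side$events$task,
               onset_sample = as.integer(side$events$onset_sample))
  } else {
    data.frame(task = character(), onset_sample = integer())
  }
  eeg_record(data, side$fs, events, side$group, side$subject)
}

# EDF import -----------------------------------------------------------------

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

#' Read an EDF/EDF+ file as an EEG record
#'
#' Minimal importer for the 16-bit EDF format: all ordinary signals must share
#' one sampling rate; an "EDF Annotations" signal, if present, is parsed for
#' onset annotations which are mapped to task names via `annotation_map`.
#'
#' @param path EDF file.
#' @param group,subject_id record metadata (EDF carries neither reliably).
#' @param annotation_map named character vector mapping annotation text to
#'   task names; unmapped annotations are dropped.
#' @return an [eeg_record].
#' @export
read_edf <- function(path, group = "control", subject_id = "edf",
                     annotation_map = c(Standard = "Standard",
                                        Novelty = "Novelty",
                                        Target = "Target")) {
  raw <- readBin(path, "raw", n = file.size(path))
  n_data_records <- as.integer(edf_field(raw, 237L, 8L))
  record_dur <- as.numeric(edf_field(raw, 245L, 8L))
  ns <- as.integer(edf_field(raw, 253L, 4L))
  off <- 256L
  get_per_signal <- function(len) {
    out <- vapply(seq_len(ns), function(i) {
      edf_field(raw, off + (i - 1L) * len + 1L, len)
    }, character(1))
    off <<- off + ns * len
    out
  }
  labels <- get_per_signal(16L)
  get_per_signal(80L)  # transducer
  get_per_signal(8L)   # physical dimension
  phys_min <- as.numeric(get_per_signal(8L))
  phys_max <- as.numeric(get_per_signal(8L))
  dig_min <- as.numeric(get_per_signal(8L))
  dig_max <- as.numeric(get_per_signal(8L))
  get_per_signal(80L)  # prefiltering
  n_samp <- as.integer(get_per_signal(8L))
  get_per_signal(32L)  # reserved
  is_annot <- labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  fs <- unique(n_samp[sig_idx] / record_dur)
  if (length(fs) != 1L) stop("mixed sampling rates not supported", call. = FALSE)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, length(sig_idx), n_data_records * n_samp[sig_idx[1]])
  annots <- character(0)
  pos <- off  # 0-based offset of the first data record
  rec_len <- sum(n_samp) * 2L
  for (r in seq_len(n_data_records)) {
    p <- pos
    for (s in seq_len(ns)) {
      nb <- n_samp[s] * 2L
      chunk <- raw[(p + 1L):(p + nb)]
      p <- p + nb
      if (is_annot[s]) {
        annots <- c(annots, rawToChar(chunk[chunk != as.raw(0)]))
      } else {
        dig <- readBin(chunk, integer(), n = n_samp[s], size = 2L,
                       signed = TRUE, endian = "little")
        j <- match(s, sig_idx)
        data[j, ((r - 1L) * n_samp[s] + 1L):(r * n_samp[s])] <-
          phys_min[s] + scale[s] * (dig - dig_min[s])
      }
    }
    pos <- pos + rec_len
  }
  rownames(data) <- labels[sig_idx]
  events <- data.frame(task = character(), onset_sample = integer())
  if (length(annots)) {
    # TAL format: "+<onset>[\x15<dur>]\x14<text>\x14"; timekeeping TALs
    # have empty text and are skipped by the match
    stream <- paste(annots, collapse = "")
    pat <- "\\+([0-9.]+)(?:\x15[0-9.]+)?\x14([^\x14]+)\x14"
    m <- gregexpr(pat, stream, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- attr(m, "capture.start")
      lens <- attr(m, "capture.length")
      for (i in seq_along(m)) {
        onset <- as.numeric(substr(stream, starts[i, 1],
                                   starts[i, 1] + lens[i, 1] - 1L))
        text <- substr(stream, starts[i, 2], starts[i, 2] + lens[i, 2] - 1L)
        if (text %in% names(annotation_map)) {
          events <- rbind(events, data.frame(
            task = unname(annotation_map[[text]]),
            onset_sample = as.integer(round(onset * fs))))
        }
      }
      events <- events[order(events$onset_sample), , drop = FALSE]
    }
  }
  eeg_record(data, fs, events, group, subject_id)
}
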
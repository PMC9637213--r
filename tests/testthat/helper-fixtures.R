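# Shared fixtures and independent oracles ------------------------------------

# toy rectangular grids
toy_grid_3x3 <- function() {
  labs <- as.vector(outer(LETTERS[1:3], 1:3, paste0))  # A1..C3, row-major A,B,C
  build_grid(data.frame(label = labs,
                        row = rep(0:2, times = 3),
                        col = rep(0:2, each = 3)))
}

toy_grid_5x5 <- function() {
  df <- expand.grid(row = 0:4, col = 0:4)
  df$label <- paste0("E", df$row, df$col)
  build_grid(df)
}

# a small record with given data and evenly spaced events of one task
make_record <- function(data, fs = 500, group = "control", id = "S1",
                        events = NULL) {
  if (is.null(events)) events <- data.frame(task = character(),
                                            onset_sample = integer())
  if (is.null(rownames(data))) {
    rownames(data) <- paste0("ch", seq_len(nrow(data)))
  }
  eeg_record(data, fs, events, group, id)
}

# constant-valued record long enough to epoch: value everywhere, n_events
# Standard events fully inside the record
constant_record <- function(value, n_ch = 3, n_events = 1, fs = 500,
                            dur_s = 4 * (n_events + 1), group = "control",
                            id = "S1", task = "Standard") {
  n <- fs * dur_s
  onsets <- as.integer(fs * (2 + 4 * seq_len(n_events) - 4 + 0.1 * seq_len(n_events)))
  data <- matrix(value, n_ch, n,
                 dimnames = list(paste0("ch", seq_len(n_ch)), NULL))
  make_record(data, fs, group, id,
              events = data.frame(task = task, onset_sample = onsets))
}

# small synthetic config on the default grid for pipeline tests
small_config <- function(..., n_per_group = 3L, seed = 11L) {
  synthetic_config(n_per_group = n_per_group, duration_s = 30,
                   events_per_task = c(Standard = 4L, Novelty = 1L, Target = 1L),
                   seed = seed, ...)
}

# --- independent oracles -----------------------------------------------------

# O(n^2) loop-based sample entropy counter, independent of the C code
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  A <- 0L; B <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        dm1 <- max(dm, abs(x[i + m] - x[j + m]))
        if (dm1 <= r) A <- A + 1L
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# brute-force top CSP filter: maximize w' Cp w / (w' (Cc + Cp) w) over unit
# vectors, by dense random + local search (independent of eigen machinery)
csp_top_filter_oracle <- function(avg_control, avg_pd, n_restarts = 40) {
  Cc <- tcrossprod(avg_control); Cc <- Cc / sum(diag(Cc))
  Cp <- tcrossprod(avg_pd); Cp <- Cp / sum(diag(Cp))
  Ctot <- Cc + Cp
  obj <- function(w) {
    nw <- sqrt(sum(w^2))
    w <- w / nw
    -(w %*% Cp %*% w) / (w %*% Ctot %*% w)
  }
  d <- nrow(Cc)
  best <- NULL; best_val <- Inf
  for (k in seq_len(n_restarts)) {
    w0 <- stats::rnorm(d)
    res <- stats::optim(w0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (res$value < best_val) {
      best_val <- res$value
      best <- res$par / sqrt(sum(res$par^2))
    }
  }
  list(w = best, ratio = -best_val)
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# --- minimal independent EDF writer (tests only) ----------------------------
# Follows the published EDF/EDF+ header layout directly; used to exercise
# read_edf() against a file the reader did not produce.
write_edf_test <- function(path, data, fs, annotations = NULL) {
  n_ch <- nrow(data)
  record_dur <- 1
  n_rec <- ncol(data) / fs
  stopifnot(n_rec == round(n_rec))
  has_ann <- !is.null(annotations)
  ns <- n_ch + has_ann
  pad <- function(x, n) {
    s <- substr(as.character(x), 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  phys_min <- -3276.8; phys_max <- 3276.7
  dig_min <- -32768L; dig_max <- 32767L
  ann_samples <- 32L  # 64 bytes per record for the annotation signal
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test subject", 80), pad("test rec", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_rec, 8), pad(record_dur, 8), pad(ns, 4))
  labels <- c(rownames(data), if (has_ann) "EDF Annotations")
  per <- function(vals, width) paste0(vapply(vals, pad, character(1), width),
                                      collapse = "")
  hdr <- paste0(hdr,
    per(labels, 16), per(rep("", ns), 80), per(rep("uV", ns), 8),
    per(rep(phys_min, ns), 8), per(rep(phys_max, ns), 8),
    per(rep(dig_min, ns), 8), per(rep(dig_max, ns), 8),
    per(rep("", ns), 80),
    per(c(rep(fs, n_ch), if (has_ann) ann_samples), 8),
    per(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(n_ch)) {
      dig <- as.integer(round(dig_min + scale * (data[ch, idx] - phys_min)))
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (has_ann) {
      tal <- paste0("+", r - 1, "\x14\x14")  # timekeeping TAL
      rows <- annotations[annotations$onset >= r - 1 & annotations$onset < r, ,
                          drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        tal <- paste0(tal, sprintf("+%g\x14%s\x14", rows$onset[k],
                                   rows$text[k]))
      }
      raw_tal <- charToRaw(tal)
      stopifnot(length(raw_tal) <= 2L * ann_samples)
      writeBin(c(raw_tal, rep(as.raw(0), 2L * ann_samples - length(raw_tal))),
               con)
    }
  }
  invisible(path)
}
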
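# Surface-Laplacian mask features -------------------------------------------
#
# Discrete Laplacian on the electrode grid: center minus one quarter of its
# four neighbors at grid distance d (d = 1 small mask, d = 2 large mask).
# A high-pass spatial operator emphasizing local cortical activity; linear
# in the input, so Laplacian-of-average equals average-of-Laplacians.

#' Specify a Laplacian mask
#'
#' @param center electrode label.
#' @param d 1 (small mask) or 2 (large mask).
#' @return object of class `laplacian_mask`.
#' @export
laplacian_mask <- function(center, d = 1L) {
  stopifnot(d %in% c(1L, 2L))
  structure(list(center = center, d = as.integer(d)), class = "laplacian_mask")
}

mask_label <- function(spec) {
  paste0(spec$center, if (spec$d == 2L) "_L" else "")
}

mask_channels <- function(grid, spec) {
  nb <- neighbors(grid, spec$center, spec$d)
  if (!nb$complete) {
    stop(sprintf("Laplacian mask at %s (d=%d) infeasible: missing %s neighbor(s)",
                 spec$center, spec$d, paste(nb$missing, collapse = ", ")),
         call. = FALSE)
  }
  nb$labels
}

#' Laplacian-filtered time series
#'
#' `y(n) = x_center(n) - (1/4) * sum of the four d-neighbors x(n)`.
#'
#' @param signals channels-by-samples matrix with channel labels as row names.
#' @param grid a `montage_grid`.
#' @param spec a [laplacian_mask()].
#' @return numeric vector of length `ncol(signals)`.
#' @export
laplacian_signal <- function(signals, grid, spec) {
  signals <- as.matrix(signals)
  nb <- mask_channels(grid, spec)
  need <- c(spec$center, nb)
  absent <- setdiff(need, rownames(signals))
  if (length(absent)) {
    stop("channel(s) not present in the data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  signals[spec$center, ] - colSums(signals[nb, , drop = FALSE]) / 4
}

#' Single-value Laplacian feature for one record and task
#'
#' Averages the record's task intervals, applies the mask, and takes the mean
#' over the interval samples.  By linearity this equals the mean of the
#' per-interval mask outputs.
#'
#' @param record a filtered [eeg_record].
#' @param task task name.
#' @param spec_interval an [interval_spec()].
#' @param mask a [laplacian_mask()].
#' @param grid a `montage_grid`.
#' @return one number (microvolts).
#' @export
laplacian_feature <- function(record, task, spec_interval, mask, grid) {
  avg <- record_task_average(record, task, spec_interval)
  mean(laplacian_signal(avg, grid, mask))
}

#' Laplacian feature vector for a set of masks
#'
#' @inheritParams laplacian_feature
#' @param masks list of [laplacian_mask()]s (order preserved); infeasible
#'   masks raise an error naming each one.
#' @return named numeric vector, one value per mask (names like `"F3"` or
#'   `"F3_L"` for the large mask).
#' @export
laplacian_feature_set <- function(record, task, spec_interval, masks, grid) {
  if (!length(masks)) return(stats::setNames(numeric(0), character(0)))
  bad <- Filter(function(m) !neighbors(grid, m$center, m$d)$complete, masks)
  if (length(bad)) {
    stop("infeasible mask(s): ",
         paste(vapply(bad, mask_label, character(1)), collapse = ", "),
         call. = FALSE)
  }
  avg <- record_task_average(record, task, spec_interval)
  vals <- vapply(masks, function(m) mean(laplacian_signal(avg, grid, m)),
                 numeric(1))
  stats::setNames(vals, vapply(masks, mask_label, character(1)))
}

#' Default candidate mask centers
#'
#' The frontal/central electrodes identified as informative by the CSP
#' patterns, plus C4 for left/right symmetry.
#'
#' @return character vector of nine labels.
#' @export
candidate_mask_centers <- function() {
  c("F3", "Fz", "F4", "FC3", "FCz", "FC4", "C3", "CPz", "C4")
}
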
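# Pooled group-average intervals --------------------------------------------
#
# The spatial-filter fit works on one averaged interval per group and task.
# Two constructions exist: the average of per-record averages, and the pooled
# average of every interval in the group (each interval weighted equally, so
# records with more intervals weigh more).  The pooled construction is the
# default throughout.

#' Average interval of one task within a record
#'
#' Elementwise mean over all of the record's intervals for the task.
#'
#' @param record a filtered [eeg_record].
#' @param task task name.
#' @param spec an [interval_spec()].
#' @return channels-by-n matrix, with attribute `n_intervals`.
#' @export
record_task_average <- function(record, task, spec) {
  ivs <- task_intervals(record, task, spec)
  if (!length(ivs)) {
    stop("record ", record$subject_id, " has no usable ", task, " intervals",
         call. = FALSE)
  }
  a <- Reduce(`+`, ivs) / length(ivs)
  attr(a, "n_intervals") <- length(ivs)
  a
}

#' Pooled average interval of a group
#'
#' `a_g = (1/z_tot) * sum over records k, intervals l of s_{g,k,l}`, where
#' `z_tot` is the total interval count of the group.  Records contributing no
#' usable intervals are dropped from `z_tot` with a warning.
#'
#' @param records list of [eeg_record]s, all of one group, sharing channel
#'   set and sampling rate.
#' @param task task name.
#' @param spec an [interval_spec()].
#' @param method `"pooled"` (default: every interval weighted equally) or
#'   `"of_averages"` (mean of the per-record averages).
#' @return object of class `group_average` with fields `a` (channels x n
#'   matrix), `group`, `task`, `spec`, `z_tot` and `per_record_counts`.
#' @export
group_pooled_average <- function(records, task, spec,
                                 method = c("pooled", "of_averages")) {
  method <- match.arg(method)
  stopifnot(length(records) >= 1)
  labs <- records[[1]]$channel_labels
  fs <- records[[1]]$fs
  for (r in records) {
    if (!identical(r$channel_labels, labs) || r$fs != fs) {
      stop("records disagree on channel set or sampling rate", call. = FALSE)
    }
  }
  group <- unique(vapply(records, `[[`, character(1), "group"))
  if (length(group) != 1L) stop("records span both groups", call. = FALSE)
  counts <- integer(0)
  acc <- NULL
  acc_avg <- NULL
  for (r in records) {
    ivs <- suppressWarnings(task_intervals(r, task, spec))
    if (!length(ivs)) {
      warning("record ", r$subject_id, " contributes no ", task,
              " intervals; dropped", call. = FALSE)
      next
    }
    s <- Reduce(`+`, ivs)
    counts <- c(counts, length(ivs))
    acc <- if (is.null(acc)) s else acc + s
    ra <- s / length(ivs)
    acc_avg <- if (is.null(acc_avg)) ra else acc_avg + ra
  }
  z_tot <- sum(counts)
  if (z_tot == 0L) stop("no usable ", task, " intervals in group", call. = FALSE)
  a <- if (method == "pooled") acc / z_tot else acc_avg / length(counts)
  rownames(a) <- labs
  structure(list(a = a, group = group, task = task, spec = spec,
                 z_tot = z_tot, per_record_counts = counts, method = method),
            class = "group_average")
}

#' @export
print.group_average <- function(x, ...) {
  cat(sprintf("<group_average> %s / %s: %d channels x %d samples, %d intervals (%s)\n",
              x$group, x$task, nrow(x$a), ncol(x$a), x$z_tot, x$method))
  invisible(x)
}
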
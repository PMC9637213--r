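# Fixed-split classifier evaluation and the parameter grid ------------------

#' Stratified learning/validation split
#'
#' Per-group rounding to the nearest integer; with 25 + 25 records at 0.6
#' this gives 15 + 15 learning and 10 + 10 validation.  The split is meant
#' to be drawn once, persisted, and reused verbatim (see [save_split()]).
#'
#' @param manifest data.frame with `subject_id` and `group`.
#' @param learning_fraction in (0, 1); default 0.6.
#' @param seed integer.
#' @return object of class `split_spec` with `learning_ids`,
#'   `validation_ids` and `counts`.
#' @export
stratified_split <- function(manifest, learning_fraction = 0.6, seed = 1L) {
  if (!(learning_fraction > 0 && learning_fraction < 1)) {
    stop("learning_fraction must be in (0, 1)", call. = FALSE)
  }
  stopifnot(all(c("subject_id", "group") %in% names(manifest)))
  learning <- character(0)
  with_seed(seed, {
    for (g in unique(manifest$group)) {
      ids <- manifest$subject_id[manifest$group == g]
      if (length(ids) < 2L) stop("need >= 2 records per group", call. = FALSE)
      n_learn <- round(length(ids) * learning_fraction)
      learning <- c(learning, sample(ids, n_learn))
    }
  })
  validation <- setdiff(manifest$subject_id, learning)
  structure(list(learning_ids = sort(learning),
                 validation_ids = sort(validation),
                 counts = table(manifest$group[match(sort(learning),
                                                     manifest$subject_id)]),
                 learning_fraction = learning_fraction, seed = seed),
            class = "split_spec")
}

split_hash <- function(split) {
  # polynomial rolling hash over the canonical id string (stays below 2^31);
  # guards the persisted split against silent edits
  s <- paste(c(split$learning_ids, "|", split$validation_ids), collapse = ",")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Persist / load a split
#'
#' The JSON carries a hash of the id lists; [load_split()] refuses a file
#' whose hash does not match, so a split drawn once cannot silently change.
#'
#' @param split a `split_spec`.
#' @param path JSON file path.
#' @export
save_split <- function(split, path) {
  jsonlite::write_json(list(learning_ids = split$learning_ids,
                            validation_ids = split$validation_ids,
                            learning_fraction = split$learning_fraction,
                            seed = split$seed,
                            hash = split_hash(split)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_split
#' @export
load_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  split <- structure(list(learning_ids = x$learning_ids,
                          validation_ids = x$validation_ids,
                          learning_fraction = x$learning_fraction,
                          seed = x$seed),
                     class = "split_spec")
  if (!identical(split_hash(split), x$hash)) {
    stop("split file hash mismatch: the persisted split was modified",
         call. = FALSE)
  }
  split
}

#' Classification metrics with PD as the positive class
#'
#' @param predicted,truth label vectors ("control"/"pd").
#' @return object of class `classifier_result`: confusion counts `tp`, `fn`,
#'   `tn`, `fp` and `accuracy`, `sensitivity`, `specificity` in percent.
#' @export
classifier_metrics <- function(predicted, truth) {
  predicted <- as_group_factor(predicted)
  truth <- as_group_factor(truth)
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == "pd" & truth == "pd")
  fn <- sum(predicted == "control" & truth == "pd")
  tn <- sum(predicted == "control" & truth == "control")
  fp <- sum(predicted == "pd" & truth == "control")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 predicted = as.character(predicted),
                 truth = as.character(truth),
                 accuracy = 100 * (tp + tn) / length(truth),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp)),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> acc %.1f%%, se %.1f%%, sp %.1f%% (TP %d FN %d TN %d FP %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Train on the learning features and evaluate on the validation features
#'
#' For the SVM kinds, features are standardized with learning-set statistics
#' first; the other classifiers consume raw features.
#'
#' @param kind classifier kind.
#' @param X_learn,y_learn,X_valid,y_valid feature matrices and labels.
#' @param hyper hyperparameters passed to [train_classifier()].
#' @return a `classifier_result` (see [classifier_metrics()]).
#' @export
evaluate_classifier <- function(kind, X_learn, y_learn, X_valid, y_valid,
                                hyper = list()) {
  X_learn <- as.matrix(X_learn)
  X_valid <- as.matrix(X_valid)
  if (startsWith(kind, "svm")) {
    mu <- colMeans(X_learn)
    sdv <- apply(X_learn, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X_learn <- sweep(sweep(X_learn, 2, mu), 2, sdv, "/")
    X_valid <- sweep(sweep(X_valid, 2, mu), 2, sdv, "/")
  }
  model <- train_classifier(kind, X_learn, y_learn, hyper)
  classifier_metrics(stats::predict(model, X_valid), y_valid)
}

# Precomputed per-record task averages --------------------------------------

#' Reduce a cohort to per-record task-average intervals
#'
#' Filters each record per band and keeps only the per-record average
#' interval for each requested interval length (all the grid needs for CSP
#' and Laplacian features), so full records need not stay in memory per band.
#'
#' @param records list of [eeg_record]s.
#' @param task task name.
#' @param high_hz vector of upper band edges (low edge fixed by `low_hz`).
#' @param length_ms vector of interval lengths.
#' @param start_ms interval start offset.
#' @param low_hz lower band edge.
#' @return nested list `averages[[as.character(high)]][[subject_id]]` =
#'   list of average matrices per length (named by length) plus
#'   `n_intervals`; with attributes `groups` and `ids`.
#' @export
cohort_task_averages <- function(records, task, high_hz = c(4, 13, 20, 30),
                                 length_ms = c(250, 500, 1000), start_ms = 0,
                                 low_hz = 0.1) {
  ids <- vapply(records, `[[`, character(1), "subject_id")
  groups <- vapply(records, `[[`, character(1), "group")
  out <- list()
  for (high in high_hz) {
    per_rec <- list()
    for (rec in records) {
      f <- bandpass(rec, low_hz, high)
      avgs <- list()
      n_iv <- NA_integer_
      for (len in length_ms) {
        a <- record_task_average(f, task, interval_spec(start_ms, len))
        n_iv <- attr(a, "n_intervals")
        avgs[[as.character(len)]] <- a
      }
      per_rec[[rec$subject_id]] <- list(avgs = avgs, n_intervals = n_iv)
    }
    out[[as.character(high)]] <- per_rec
  }
  attr(out, "ids") <- ids
  attr(out, "groups") <- stats::setNames(groups, ids)
  out
}

# pooled group average reconstructed from record averages and counts
pooled_from_averages <- function(per_rec, ids, len) {
  num <- NULL
  z <- 0L
  for (id in ids) {
    e <- per_rec[[id]]
    s <- e$avgs[[as.character(len)]] * e$n_intervals
    num <- if (is.null(num)) s else num + s
    z <- z + e$n_intervals
  }
  num / z
}

log_var_features <- function(model, avg, components) {
  Z <- csp_project(model, avg)
  idx <- match(components, model$component_names)
  v <- apply(Z[idx, , drop = FALSE], 1, function(z) mean((z - mean(z))^2))
  stats::setNames(log(v), components)
}

#' Default grid feature sets
#'
#' CSP component subsets over the six extreme components and Laplacian mask
#' combinations over the nine candidate centers (all singles, small and
#' large where feasible, plus the two multi-mask combinations highlighted by
#' the analysis: Fz + large F3 + large F4, and Fz + large C3).
#'
#' @param grid montage used to drop infeasible masks.
#' @param types subset of `c("csp", "laplacian")`.
#' @return named list of feature-set specs for [run_grid()].
#' @export
default_feature_sets <- function(grid = default_layout_60(),
                                 types = c("csp", "laplacian")) {
  sets <- list()
  if ("csp" %in% types) {
    for (comp in list("MxPMnC1", "MxPMnC2", "MxPMnC3",
                      c("MxPMnC1", "MxPMnC2"), c("MxPMnC2", "MxPMnC3"),
                      c("MxPMnC1", "MxPMnC2", "MxPMnC3"),
                      "MnPMxC1", c("MnPMxC1", "MnPMxC2", "MnPMxC3"))) {
      sets[[paste(comp, collapse = "+")]] <- list(type = "csp", components = comp)
    }
  }
  if ("laplacian" %in% types) {
    masks <- list()
    for (ctr in candidate_mask_centers()) {
      if (!ctr %in% names(grid$label_to_cell)) next
      for (d in 1:2) {
        m <- laplacian_mask(ctr, d)
        if (neighbors(grid, ctr, d)$complete) masks[[mask_label(m)]] <- m
      }
    }
    specs <- c(lapply(names(masks), function(nm) masks[nm]),
               list(masks[c("Fz", "F3_L", "F4_L")], masks[c("Fz", "C3_L")]))
    for (sp in specs) {
      sp <- Filter(Negate(is.null), sp)
      if (length(sp)) {
        sets[[paste(names(sp), collapse = "+")]] <-
          list(type = "laplacian", masks = sp)
      }
    }
  }
  sets
}

#' Run the parameter grid
#'
#' Cartesian product of band upper edge x interval length x feature set x
#' classifier.  The CSP transformation and any feature standardization are
#' fitted on learning records only and applied to the validation records.
#'
#' @param records list of [eeg_record]s (unfiltered).
#' @param manifest cohort manifest (`subject_id`, `group`).
#' @param split a `split_spec`.
#' @param grid montage grid for Laplacian masks.
#' @param task task name (default "Standard").
#' @param high_hz,length_ms,start_ms grid axes.
#' @param feature_sets named list of feature-set specs
#'   (see [default_feature_sets()]).
#' @param classifiers classifier kinds to include.
#' @param averages optional precomputed [cohort_task_averages()] (must cover
#'   the axes); computed here when `NULL`.
#' @return long-format data.frame: one row per grid cell with the metrics
#'   and confusion counts.
#' @export
run_grid <- function(records, manifest, split, grid = default_layout_60(),
                     task = "Standard",
                     high_hz = c(4, 13, 20, 30),
                     length_ms = c(250, 500, 1000),
                     start_ms = 0,
                     feature_sets = default_feature_sets(grid),
                     classifiers = classifier_kinds(),
                     averages = NULL) {
  if (is.null(averages)) {
    averages <- cohort_task_averages(records, task, high_hz, length_ms, start_ms)
  }
  groups <- attr(averages, "groups")
  learn_ids <- split$learning_ids
  valid_ids <- split$validation_ids
  rows <- list()
  for (high in high_hz) {
    per_rec <- averages[[as.character(high)]]
    for (len in length_ms) {
      # CSP model from the learning set only
      model <- NULL
      if (any(vapply(feature_sets, function(s) s$type == "csp", logical(1)))) {
        avg_c <- pooled_from_averages(per_rec,
                                      learn_ids[groups[learn_ids] == "control"], len)
        avg_p <- pooled_from_averages(per_rec,
                                      learn_ids[groups[learn_ids] == "pd"], len)
        model <- suppressWarnings(csp_fit(avg_c, avg_p))
      }
      for (set_name in names(feature_sets)) {
        set <- feature_sets[[set_name]]
        feat <- function(id) {
          avg <- per_rec[[id]]$avgs[[as.character(len)]]
          if (set$type == "csp") {
            log_var_features(model, avg, set$components)
          } else {
            vapply(set$masks, function(m) mean(laplacian_signal(avg, grid, m)),
                   numeric(1))
          }
        }
        X_learn <- do.call(rbind, lapply(learn_ids, feat))
        X_valid <- do.call(rbind, lapply(valid_ids, feat))
        for (clf in classifiers) {
          res <- evaluate_classifier(clf, X_learn, groups[learn_ids],
                                     X_valid, groups[valid_ids])
          rows[[length(rows) + 1L]] <- data.frame(
            high_hz = high, length_ms = len, start_ms = start_ms,
            feature_set = set_name, type = set$type, classifier = clf,
            accuracy = res$accuracy, sensitivity = res$sensitivity,
            specificity = res$specificity,
            tp = res$tp, fn = res$fn, tn = res$tn, fp = res$fp)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Selection-adjusted null band for validation accuracy
#'
#' Bonferroni-adjusted two-sided binomial band around 50% for the best (or
#' worst) accuracy over `n_configs` grid cells on `n_validation` records
#' when the groups are exchangeable.
#'
#' @param n_validation validation-set size.
#' @param n_configs number of grid cells searched.
#' @param level overall coverage (default 0.95).
#' @return `c(lower, upper)` in percent.
#' @export
null_accuracy_band <- function(n_validation, n_configs, level = 0.95) {
  alpha <- (1 - level) / n_configs / 2
  c(lower = 100 * stats::qbinom(alpha, n_validation, 0.5) / n_validation,
    upper = 100 * stats::qbinom(1 - alpha, n_validation, 0.5) / n_validation)
}
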
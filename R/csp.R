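# Common Spatial Patterns ----------------------------------------------------
#
# CSP finds linear channel combinations whose variance is maximal for one
# class and minimal for the other.  Fit on the two group-average intervals:
# (1) trace-normalized covariance per class, (2) whiten the composite
# covariance, (3) diagonalize the whitened PD covariance.  Rows of W are
# spatial filters; columns of its inverse are spatial patterns (the scalp
# projection of each component, the thing a topographic plot shows).

#' Trace-normalized covariance of an interval matrix
#'
#' `C = E %*% t(E) / trace(E %*% t(E))`; symmetric PSD with unit trace.
#'
#' @param E channels-by-samples matrix.
#' @return channels-by-channels matrix.
#' @export
normalized_covariance <- function(E) {
  E <- as.matrix(E)
  stopifnot(ncol(E) >= 2)
  C <- tcrossprod(E)
  tr <- sum(diag(C))
  if (tr <= 0) stop("degenerate input: zero total power", call. = FALSE)
  C / tr
}

#' Fit a CSP model from the two group averages
#'
#' Components are ordered by the PD-class variance ratio, descending: the
#' first three are the maximized-PD / minimized-control components
#' (`MxPMnC1..3`), the last three the reverse (`MnPMxC1..3`).
#'
#' @param avg_control,avg_pd channels-by-samples matrices (e.g. `a` from
#'   [group_pooled_average()]) sharing row order; row names are channel labels.
#' @param reg_eps Tikhonov load applied as `reg_eps * trace` on the composite
#'   covariance when it is numerically rank deficient.
#' @return object of class `csp_model`: `W` (components x channels filters),
#'   `patterns` (channels x components, inverse of `W`), `ratios` (per
#'   component, fraction of PD variance; complements sum to 1 with the
#'   control fraction), `channel_labels`, `component_names`.
#' @export
csp_fit <- function(avg_control, avg_pd, reg_eps = 1e-10) {
  avg_control <- as.matrix(avg_control)
  avg_pd <- as.matrix(avg_pd)
  if (!is.null(rownames(avg_control)) && !is.null(rownames(avg_pd)) &&
      !identical(rownames(avg_control), rownames(avg_pd))) {
    stop("channel labels of the two averages differ", call. = FALSE)
  }
  stopifnot(nrow(avg_control) == nrow(avg_pd))
  labs <- rownames(avg_control)
  if (is.null(labs)) labs <- paste0("ch", seq_len(nrow(avg_control)))
  C_control <- normalized_covariance(avg_control)
  C_pd <- normalized_covariance(avg_pd)
  C_c <- C_control + C_pd
  eg <- eigen(C_c, symmetric = TRUE)
  tol <- max(eg$values) * length(eg$values) * .Machine$double.eps
  if (min(eg$values) < tol) {
    warning("composite covariance is rank deficient; Tikhonov regularization applied",
            call. = FALSE)
    C_c <- C_c + diag(reg_eps * sum(diag(C_c)), nrow(C_c))
    eg <- eigen(C_c, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)  # whitening: P C_c P' = I
  S_pd <- P %*% C_pd %*% t(P)
  S_pd <- (S_pd + t(S_pd)) / 2
  eb <- eigen(S_pd, symmetric = TRUE)   # eigenvalues descending (stable order)
  W <- t(eb$vectors) %*% P
  ratios <- eb$values
  patterns <- solve(W)
  # sign convention: largest-|weight| pattern entry positive, per component
  for (j in seq_len(ncol(patterns))) {
    i <- which.max(abs(patterns[, j]))
    if (patterns[i, j] < 0) {
      patterns[, j] <- -patterns[, j]
      W[j, ] <- -W[j, ]
    }
  }
  n <- nrow(W)
  comp_names <- paste0("comp", seq_len(n))
  if (n >= 6L) {
    comp_names[1:3] <- paste0("MxPMnC", 1:3)
    comp_names[(n - 2L):n] <- paste0("MnPMxC", 3:1)
  }
  rownames(W) <- comp_names
  colnames(W) <- labs
  rownames(patterns) <- labs
  colnames(patterns) <- comp_names
  structure(list(W = W, patterns = patterns, ratios = ratios,
                 channel_labels = labs, component_names = comp_names),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels; top PD-variance ratios: %s\n",
              length(x$channel_labels),
              paste(sprintf("%.3f", utils::head(x$ratios, 3)), collapse = ", ")))
  invisible(x)
}

#' Map channel-space signals into component space
#'
#' @param model a [csp_fit()] model.
#' @param signals channels-by-samples matrix in the model's channel order.
#' @return components-by-samples matrix `W %*% signals`.
#' @export
csp_project <- function(model, signals) {
  signals <- as.matrix(signals)
  if (!is.null(rownames(signals)) &&
      !identical(rownames(signals), model$channel_labels)) {
    stop("signal channel labels do not match the model", call. = FALSE)
  }
  stopifnot(nrow(signals) == ncol(model$W))
  model$W %*% signals
}

#' Spatial patterns of the six extreme components
#'
#' @param model a [csp_fit()] model.
#' @return channels-by-6 matrix: columns `MxPMnC1..3` then `MnPMxC1..3`.
#' @export
spatial_patterns <- function(model) {
  n <- ncol(model$patterns)
  stopifnot(n >= 6L)
  model$patterns[, c(1:3, n:(n - 2L)), drop = FALSE]
}

#' Log-variance CSP features of one record
#'
#' For each selected component: natural log of the population variance of the
#' component signal over the task interval.  `avg_then_map` (default)
#' averages the record's intervals first and projects the average;
#' `map_then_avg` projects every interval and averages the projections —
#' both are linear, so they agree, but both are provided as stated modes.
#'
#' @param model a [csp_fit()] model.
#' @param record a filtered [eeg_record].
#' @param task task name.
#' @param spec an [interval_spec()].
#' @param components character vector of component names (e.g.
#'   `c("MxPMnC2", "MxPMnC3")`) or integer indices into the ordering.
#' @param mode `"avg_then_map"` or `"map_then_avg"`.
#' @return named feature vector, one log-variance per component.
#' @export
csp_features <- function(model, record, task, spec,
                         components = c("MxPMnC1", "MxPMnC2", "MxPMnC3"),
                         mode = c("avg_then_map", "map_then_avg")) {
  mode <- match.arg(mode)
  if (is.character(components)) {
    idx <- match(components, model$component_names)
    if (anyNA(idx)) {
      stop("unknown component(s): ",
           paste(components[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(components)
  }
  if (mode == "avg_then_map") {
    avg <- record_task_average(record, task, spec)
    Z <- csp_project(model, avg)
  } else {
    ivs <- task_intervals(record, task, spec)
    if (!length(ivs)) {
      stop("record ", record$subject_id, " has no usable ", task, " intervals",
           call. = FALSE)
    }
    Zs <- lapply(ivs, function(iv) csp_project(model, iv))
    Z <- Reduce(`+`, Zs) / length(Zs)
  }
  v <- apply(Z[idx, , drop = FALSE], 1, function(z) mean((z - mean(z))^2))
  if (any(v <= 0)) {
    stop("zero-variance component signal; log-variance feature undefined",
         call. = FALSE)
  }
  stats::setNames(log(v), model$component_names[idx])
}

#' Rank channels by informativeness of the extreme spatial patterns
#'
#' Quantifies the visual reading of topographic pattern plots: a channel is
#' informative when a pattern loads strongly on it and changes sharply in its
#' neighborhood.  Per channel and extreme component the score is
#' `|weight| + mean |weight - neighbor weight|` over the d=1 grid neighbors,
#' on the raw pattern weights (so components carrying more signal variance
#' contribute larger scores); the channel score is the max over the six
#' components, rescaled to [0, 1].
#'
#' @param patterns channels-by-components matrix (e.g. [spatial_patterns()]).
#' @param grid a `montage_grid` resolving the pattern channels.
#' @return data.frame with `channel` and `score`, sorted by score descending.
#' @export
rank_informative_channels <- function(patterns, grid) {
  patterns <- as.matrix(patterns)
  labs <- rownames(patterns)
  stopifnot(!is.null(labs))
  on_grid <- labs %in% names(grid$label_to_cell)
  score <- stats::setNames(numeric(length(labs)), labs)
  for (j in seq_len(ncol(patterns))) {
    w <- patterns[, j]
    for (i in which(on_grid)) {
      nb <- neighbors(grid, labs[i], 1L)$labels
      nb <- nb[!is.na(nb) & nb %in% labs]
      grad <- if (length(nb)) mean(abs(w[i] - w[nb])) else 0
      score[i] <- max(score[i], abs(w[i]) + grad)
    }
  }
  if (max(score) > 0) score <- score / max(score)
  out <- data.frame(channel = labs, score = unname(score))
  out[order(-out$score, out$channel), , drop = FALSE]
}
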
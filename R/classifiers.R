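# Two-class classifiers ------------------------------------------------------
#
# Six classifier kinds: SVM with polynomial or RBF kernel (a compact SMO
# implementation; no external SVM library is assumed), Gaussian naive Bayes,
# LDA and QDA (via MASS), and a small deterministic CART decision tree.
# Labels are always the two groups, "control" and "pd".

GROUP_LEVELS <- c("control", "pd")

#' Available classifier kinds
#' @return character vector.
#' @export
classifier_kinds <- function() {
  c("svm_poly", "svm_rbf", "bayes", "lda", "qda", "tree")
}

as_group_factor <- function(y) {
  y <- as.character(y)
  stopifnot(all(y %in% GROUP_LEVELS))
  factor(y, levels = GROUP_LEVELS)
}

#' Train a classifier
#'
#' @param kind one of [classifier_kinds()].
#' @param X numeric matrix, one row per record.
#' @param y labels ("control"/"pd"); both classes must be present.
#' @param hyper named list of hyperparameters; recognized: `C` (SVM margin
#'   cost, default 1), `degree` (polynomial degree, 3), `gamma` (kernel
#'   scale; default `1 / (p * var(X))`), `coef0` (polynomial offset, 1),
#'   `min_leaf` and `max_depth` for the tree.
#' @return a model object with a `predict` method returning labels.
#' @export
train_classifier <- function(kind, X, y, hyper = list()) {
  kind <- match.arg(kind, classifier_kinds())
  X <- as.matrix(X)
  y <- as_group_factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (all(apply(X, 2, function(col) diff(range(col)) == 0))) {
    # degenerate: no information in the features; fall back to majority class
    maj <- names(sort(table(y), decreasing = TRUE))[1]
    return(structure(list(kind = kind, majority = maj),
                     class = c("majority_model", "eegcsp_model")))
  }
  model <- switch(kind,
    lda = MASS::lda(X, grouping = y),
    qda = MASS::qda(X, grouping = y),
    bayes = fit_gnb(X, y),
    tree = fit_cart(X, y,
                    min_leaf = hyper$min_leaf %||% 2L,
                    max_depth = hyper$max_depth %||% 10L),
    svm_poly = ,
    svm_rbf = fit_svm(X, y, kernel = sub("svm_", "", kind),
                      C = hyper$C %||% 1,
                      degree = hyper$degree %||% 3,
                      gamma = hyper$gamma %||% (1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))),
                      coef0 = hyper$coef0 %||% 1)
  )
  structure(list(kind = kind, fit = model),
            class = c(paste0(kind, "_model"), "eegcsp_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.eegcsp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- switch(object$kind,
    lda = ,
    qda = as.character(stats::predict(object$fit, X)$class),
    bayes = predict_gnb(object$fit, X),
    tree = predict_cart(object$fit, X),
    svm_poly = ,
    svm_rbf = predict_svm(object$fit, X)
  )
  factor(out, levels = GROUP_LEVELS)
}

#' @export
predict.majority_model <- function(object, newdata, ...) {
  factor(rep(object$majority, nrow(as.matrix(newdata))), levels = GROUP_LEVELS)
}

# Gaussian naive Bayes --------------------------------------------------------

fit_gnb <- function(X, y) {
  classes <- levels(y)
  stats_by <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    v <- apply(Xc, 2, stats::var)
    v[!is.finite(v) | v < 1e-12] <- 1e-12
    list(mean = colMeans(Xc), var = v, prior = mean(y == cl))
  })
  names(stats_by) <- classes
  stats_by
}

predict_gnb <- function(fit, X) {
  ll <- vapply(names(fit), function(cl) {
    s <- fit[[cl]]
    rowSums(vapply(seq_len(ncol(X)), function(j) {
      stats::dnorm(X[, j], s$mean[j], sqrt(s$var[j]), log = TRUE)
    }, numeric(nrow(X)))) + log(s$prior)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) ll <- matrix(ll, nrow = 1, dimnames = list(NULL, names(fit)))
  names(fit)[max.col(ll, ties.method = "first")]
}

# CART decision tree ----------------------------------------------------------
#
# Exhaustive binary splits at feature midpoints, Gini impurity, deterministic
# tie-breaking (first feature, lowest threshold).

gini <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

fit_cart <- function(X, y, min_leaf = 2L, max_depth = 10L, depth = 0L) {
  n <- length(y)
  maj <- names(sort(table(y), decreasing = TRUE))[1]
  if (n < 2L * min_leaf || depth >= max_depth || gini(y) == 0) {
    return(list(leaf = TRUE, label = maj))
  }
  best <- NULL
  best_imp <- gini(y) - 1e-9  # require strict improvement
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2L) next
    for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
      left <- X[, j] <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      imp <- (nl * gini(y[left]) + (n - nl) * gini(y[!left])) / n
      if (imp < best_imp) {
        best_imp <- imp
        best <- list(j = j, thr = thr, left = left)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, label = maj))
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = fit_cart(X[best$left, , drop = FALSE], y[best$left],
                       min_leaf, max_depth, depth + 1L),
       right = fit_cart(X[!best$left, , drop = FALSE], y[!best$left],
                        min_leaf, max_depth, depth + 1L))
}

predict_cart_one <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$j] <= node$thr) node$left else node$right
  }
  node$label
}

predict_cart <- function(fit, X) {
  vapply(seq_len(nrow(X)), function(i) predict_cart_one(fit, X[i, ]),
         character(1))
}

# Kernel SVM via SMO -----------------------------------------------------------

svm_kernel <- function(kernel, gamma, degree, coef0) {
  switch(kernel,
    rbf = function(A, B) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      exp(-gamma * pmax(d2, 0))
    },
    poly = function(A, B) (gamma * tcrossprod(A, B) + coef0)^degree
  )
}

fit_svm <- function(X, y, kernel, C = 1, degree = 3, gamma = 1, coef0 = 1,
                    tol = 1e-3, max_passes = 50L) {
  yy <- ifelse(y == "pd", 1, -1)
  n <- nrow(X)
  kfun <- svm_kernel(kernel, gamma, degree, coef0)
  K <- kfun(X, X)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.vector(K %*% (alpha * yy)) + b
  passes <- 0L
  while (passes < max_passes) {
    changed <- 0L
    E <- fcache() - yy
    for (i in seq_len(n)) {
      Ei <- sum(K[, i] * alpha * yy) + b - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        Ej_all <- as.vector(K %*% (alpha * yy)) + b - yy
        j <- which.max(abs(Ei - Ej_all) + ifelse(seq_len(n) == i, -Inf, 0))
        Ej <- Ej_all[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-6) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  sv <- alpha > 1e-8
  list(X = X[sv, , drop = FALSE], alpha_y = (alpha * yy)[sv], b = b,
       kfun = kfun)
}

predict_svm <- function(fit, X) {
  if (!nrow(fit$X)) return(rep("control", nrow(X)))
  f <- as.vector(fit$kfun(X, fit$X) %*% fit$alpha_y) + fit$b
  ifelse(f > 0, "pd", "control")
}
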
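#' Radial basis function kernel
#'
#' `K(xi, x) = exp(-gamma * ||xi - x||^2)`; values lie in (0, 1] and equal
#' 1 only at zero distance. `gamma` controls locality, the soft-margin
#' penalty `C` (see [svm_params()]) controls regularisation.
#'
#' @param xi,x Equal-length numeric feature vectors.
#' @param gamma Positive kernel width parameter.
#' @return A scalar in (0, 1].
#' @export
rbf_kernel <- function(xi, x, gamma) {
  if (length(xi) != length(x)) {
    stop("`xi` and `x` must have equal length", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  exp(-gamma * sum((as.numeric(xi) - as.numeric(x))^2))
}

#' SVM hyperparameters
#'
#' @param C Soft-margin penalty factor (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An `svm_params` list.
#' @export
svm_params <- function(C, gamma) {
  if (!is.numeric(C) || C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  structure(list(C = as.numeric(C), gamma = as.numeric(gamma)),
            class = "svm_params")
}

# kernel matrix between rows of A and rows of B
rbf_kernel_matrix <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Train a multiclass RBF-SVM
#'
#' Solves the soft-margin dual problem for every class pair (one-vs-one)
#' at the given `(C, gamma)`. Features are z-score standardized on the
#' training data and the scaler is stored with the model, so new data is
#' standardized identically at prediction time. The quadratic program is
#' solved by libsvm (via e1071); the fitted dual coefficients, support
#' vectors and biases are extracted into the returned model and the dual
#' box constraint (`|alpha_i y_i| <= C`) and equality constraint
#' (`sum alpha_i y_i = 0` per pair) are verified before returning.
#'
#' @param ds Labelled dataset: a tibble/data frame with a `label` column
#'   and numeric feature columns.
#' @param params An [svm_params()].
#' @return A `posture_svm` model with elements `support_vectors` (in
#'   standardized feature space), `dual_coefs`, `rho` (per-pair biases are
#'   `-rho`), `n_sv`, `class_order`, `params`, `scaler` and
#'   `feature_names`.
#' @export
train_svm <- function(ds, params) {
  validate_dataset(ds)
  if (!inherits(params, "svm_params")) params <- do.call(svm_params, as.list(params))
  y <- as.character(ds$label)
  if (length(unique(y)) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }
  x <- as.matrix(dataset_features(ds))
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  yf <- factor(y)
  fit <- e1071::svm(x = xs, y = yf, scale = FALSE, kernel = "radial",
                    cost = params$C, gamma = params$gamma)

  class_order <- fit$levels[fit$labels]   # libsvm-internal class ordering
  model <- structure(
    list(support_vectors = as.matrix(fit$SV),
         dual_coefs = as.matrix(fit$coefs),
         rho = as.numeric(fit$rho),
         n_sv = as.integer(fit$nSV),
         class_order = class_order,
         classes = sort(unique(y)),
         params = params,
         scaler = scaler,
         feature_names = colnames(x)),
    class = "posture_svm"
  )
  check_dual_constraints(model)
  model
}

#' Verify the dual feasibility of a trained model
#'
#' Checks, for every one-vs-one subproblem, that each signed dual
#' coefficient lies in `[-C, C]` and that the coefficients sum to zero
#' (the dual equality constraint), within `tol`.
#'
#' @param model A `posture_svm`.
#' @param tol Absolute tolerance (default 1e-6).
#' @return `TRUE` invisibly; errors if a constraint is violated.
#' @export
check_dual_constraints <- function(model, tol = 1e-6) {
  C <- model$params$C
  if (any(abs(model$dual_coefs) > C + tol)) {
    stop("dual box constraint violated: |alpha_i y_i| > C", call. = FALSE)
  }
  k <- length(model$class_order)
  offs <- cumsum(c(0L, model$n_sv))
  p <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p <- p + 1L
      ci <- model$dual_coefs[seq.int(offs[i] + 1L, offs[i + 1L]), j - 1L]
      cj <- model$dual_coefs[seq.int(offs[j] + 1L, offs[j + 1L]), i]
      if (abs(sum(ci) + sum(cj)) > tol) {
        stop("dual equality constraint violated for class pair ",
             model$class_order[i], "/", model$class_order[j], call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# per-pair decision values for standardized inputs: matrix n x n_pairs
pairwise_decisions <- function(model, xs) {
  K <- rbf_kernel_matrix(xs, model$support_vectors, model$params$gamma)
  k <- length(model$class_order)
  offs <- cumsum(c(0L, model$n_sv))
  n_pairs <- (k * (k - 1L)) %/% 2L
  dec <- matrix(0, nrow(xs), n_pairs)
  pairs <- matrix(0L, n_pairs, 2L)
  p <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p <- p + 1L
      ri <- seq.int(offs[i] + 1L, offs[i + 1L])
      rj <- seq.int(offs[j] + 1L, offs[j + 1L])
      dec[, p] <- K[, ri, drop = FALSE] %*% model$dual_coefs[ri, j - 1L] +
        K[, rj, drop = FALSE] %*% model$dual_coefs[rj, i] - model$rho[p]
      pairs[p, ] <- c(i, j)
    }
  }
  list(decisions = dec, pairs = pairs)
}

#' Predict class labels with a trained model
#'
#' Evaluates the decision function
#' `f(x) = sgn(sum_i alpha_i y_i K(x_i, x) + b)` for every class pair from
#' the stored support vectors and dual coefficients, then takes a majority
#' vote over the pairwise decisions. Ties are broken by the largest
#' aggregate decision margin, then lexicographic label order.
#'
#' @param object A `posture_svm`.
#' @param newdata A data frame/tibble of features (a `label` column, if
#'   present, is ignored) or a numeric matrix with the training feature
#'   columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.posture_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- newdata[, setdiff(names(newdata), "label"), drop = FALSE]
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing)) {
      stop("newdata is missing feature columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names)) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 length(object$feature_names), ncol(newdata)), call. = FALSE)
  }
  xs <- apply_scaler(newdata, object$scaler)
  pd <- pairwise_decisions(object, xs)
  k <- length(object$class_order)
  vapply(seq_len(nrow(xs)), function(r) {
    votes <- numeric(k)
    margin <- numeric(k)
    for (p in seq_len(nrow(pd$pairs))) {
      i <- pd$pairs[p, 1L]; j <- pd$pairs[p, 2L]
      d <- pd$decisions[r, p]
      if (d > 0) votes[i] <- votes[i] + 1 else votes[j] <- votes[j] + 1
      margin[i] <- margin[i] + d
      margin[j] <- margin[j] - d
    }
    best <- which(votes == max(votes))
    if (length(best) > 1L) best <- best[margin[best] == max(margin[best])]
    if (length(best) > 1L) best <- best[order(object$class_order[best])][1L]
    object$class_order[best[1L]]
  }, character(1))
}

#' @export
print.posture_svm <- function(x, ...) {
  cat(sprintf(
    "<posture_svm> %d classes, %d support vectors, C = %g, gamma = %g\n",
    length(x$class_order), nrow(x$support_vectors), x$params$C,
    x$params$gamma
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.posture_svm <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_order),
    n_support_vectors = nrow(x$support_vectors),
    n_features = length(x$feature_names),
    C = x$params$C,
    gamma = x$params$gamma
  )
}

# deterministic stratified fold assignment; returns integer fold ids
stratified_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  if (any(counts < folds)) {
    small <- names(counts)[counts < folds][1L]
    stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                 small, counts[[small]], folds), call. = FALSE)
  }
  ids <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      ids[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  ids
}

#' Cross-validated accuracy of an (C, gamma) setting
#'
#' Stratified k-fold cross-validation: the feature scaler and the SVM are
#' refitted on each training fold and scored on the held-out fold; the
#' returned fitness is the mean held-out accuracy. Fold assignment is
#' deterministic given `seed`.
#'
#' @param ds Labelled dataset tibble.
#' @param params An [svm_params()].
#' @param folds Number of folds (default 5); every class must have at
#'   least this many samples.
#' @param seed Integer seed controlling fold assignment.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(ds, params, folds = 5L, seed = 1L) {
  validate_dataset(ds)
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  labels <- as.character(ds$label)
  ids <- stratified_folds(labels, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    train <- ds[ids != f, , drop = FALSE]
    test <- ds[ids == f, , drop = FALSE]
    model <- train_svm(train, params)
    mean(predict(model, test) == test$label)
  }, numeric(1))
  mean(acc)
}
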
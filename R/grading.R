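#' Bundle per-video feature vectors with class labels
#'
#' @param vectors List of equal-length numeric vectors (e.g.
#'   [feature_vector()] outputs) or a numeric matrix with one row per
#'   video.
#' @param labels Class label per video (coerced to factor; at least two
#'   classes).
#' @return List of class `cohort_features` with a numeric matrix `x`
#'   (videos by features) and factor `labels`.
#' @export
cohort_features <- function(vectors, labels) {
  if (is.list(vectors)) {
    len <- vapply(vectors, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("all feature vectors must have the same length", call. = FALSE)
    }
    x <- do.call(rbind, lapply(vectors, as.numeric))
  } else {
    x <- as.matrix(vectors)
  }
  labels <- factor(labels)
  if (nrow(x) != length(labels)) {
    stop("`labels` must have one entry per feature vector", call. = FALSE)
  }
  if (nlevels(labels) < 2L) stop("need at least two classes", call. = FALSE)
  structure(list(x = x, labels = labels), class = "cohort_features")
}

#' Pairwise Euclidean distance matrix between feature vectors
#'
#' @param cf A [cohort_features()].
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(cf) {
  stopifnot(inherits(cf, "cohort_features"))
  as.matrix(dist(cf$x, method = "euclidean"))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix into `dim` coordinates by double-centering the
#' squared distances and scaling the leading eigenvectors by the square
#' roots of their eigenvalues. Deterministic up to sign/rotation. If fewer
#' than `dim` positive eigenvalues exist, the remaining coordinates are
#' zero and the result is flagged.
#'
#' @param D Symmetric non-negative matrix with zero diagonal.
#' @param dim Embedding dimension (default 2).
#' @return Numeric matrix (items by `dim`) with attributes `eig`
#'   (eigenvalues) and `flagged` (`TRUE` if positive eigenvalues < `dim`).
#' @export
mds_embed <- function(D, dim = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(D < 0) || any(abs(diag(D)) > 1e-12) ||
      max(abs(D - t(D))) > 1e-8) {
    stop("`D` must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  }
  fit <- cmdscale(stats::as.dist(D), k = dim, eig = TRUE)
  pts <- fit$points
  npos <- sum(fit$eig > 1e-8 * max(abs(fit$eig)))
  flagged <- npos < dim
  if (ncol(pts) < dim) {
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  }
  structure(pts, eig = fit$eig, flagged = flagged)
}

#' Train/test motility grading with a linear SVM
#'
#' Splits each class at random (seeded) into disjoint training and test
#' videos, standardizes the features using training statistics only, trains
#' a linear support vector machine (cost 1), and reports held-out accuracy
#' with a per-class breakdown.
#'
#' @param cf A [cohort_features()].
#' @param n_train_per_class,n_test_per_class Videos drawn per class for
#'   training and testing (disjoint).
#' @param seed Integer seed for the split.
#' @return List of class `grading_result`: `accuracy`, `per_class` (named
#'   accuracy per true class), `confusion` (table), `n_train`, `n_test`.
#' @export
classify_cohort <- function(cf, n_train_per_class = 20L,
                            n_test_per_class = 20L, seed = 1L) {
  stopifnot(inherits(cf, "cohort_features"))
  need <- n_train_per_class + n_test_per_class
  counts <- table(cf$labels)
  if (any(counts < need)) {
    stop(sprintf("every class needs at least %d videos", need), call. = FALSE)
  }
  idx_train <- integer(0)
  idx_test <- integer(0)
  with_seed(seed, {
    for (lv in levels(cf$labels)) {
      pool <- which(cf$labels == lv)
      pick <- sample(pool, need)
      idx_train <- c(idx_train, pick[seq_len(n_train_per_class)])
      idx_test <- c(idx_test, pick[n_train_per_class + seq_len(n_test_per_class)])
    }
  })
  xtr <- cf$x[idx_train, , drop = FALSE]
  xte <- cf$x[idx_test, , drop = FALSE]
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, sd)
  sdev[sdev == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
  fit <- e1071::svm(x = xtr, y = cf$labels[idx_train], kernel = "linear",
                    cost = 1, scale = FALSE)
  pred <- predict(fit, xte)
  truth <- cf$labels[idx_test]
  confusion <- table(truth = truth, predicted = pred)
  per_class <- diag(prop.table(confusion, 1))
  structure(
    list(accuracy = mean(pred == truth),
         per_class = per_class,
         confusion = confusion,
         n_train = length(idx_train),
         n_test = length(idx_test)),
    class = "grading_result"
  )
}

#' @export
print.grading_result <- function(x, ...) {
  cat(sprintf("<grading_result> accuracy %.1f%% on %d held-out videos (%d trained)\n",
              100 * x$accuracy, x$n_test, x$n_train))
  print(x$confusion)
  invisible(x)
}
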
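# Linear soft-margin SVM, solved in the dual by coordinate descent
# (L2-regularized L1-loss; Hsieh-style updates). Self-contained because the
# observation counts here are tiny (tens) relative to feature counts
# (pooled cells), where a linear maximum-margin classifier is the
# conservative choice.

# Binary solver. x: n x d (bias handled via augmented constant column),
# y in {-1, +1}. Per-sample costs are inversely proportional to class size
# (class-weighted C), correcting the one-observation class imbalance that
# leave-one-out folds create. Returns the primal weight vector.
svm_solve_binary <- function(x, y, cost = 1, max_pass = 200, tol = 1e-4) {
  n_pos <- sum(y > 0)
  n_neg <- length(y) - n_pos
  ci <- cost * ifelse(y > 0, length(y) / (2 * n_pos),
                      length(y) / (2 * n_neg))
  svm_cd_solve(cbind(x, 1), y, ci, as.integer(max_pass), tol)
}

#' Train a linear SVM (one-vs-one multiclass)
#'
#' Features are standardized (centre/scale, zero-variance columns scaled by
#' 1) using the training data only; a binary maximum-margin hyperplane with
#' class-weighted costs (inverse class frequency, so unbalanced folds do not
#' bias the margin) is fitted for every unordered class pair; prediction is
#' by majority vote with ties broken by summed decision values, then by
#' class order.
#'
#' @param x Numeric matrix, observations x features.
#' @param y Class labels (coerced to character).
#' @param cost Soft-margin cost parameter C.
#' @param standardize Standardize features from the training set (default).
#' @return Object of class \code{linear_svm}.
#' @export
svm_train <- function(x, y, cost = 1, standardize = TRUE) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (standardize) {
    n <- nrow(x)
    ctr <- colMeans(x)
    scl <- sqrt(pmax(colSums(x^2) - n * ctr^2, 0) / (n - 1))
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    yy <- ifelse(y[sel] == p[1L], 1, -1)
    svm_solve_binary(xs[sel, , drop = FALSE], yy, cost = cost)
  })
  structure(list(classes = classes, pairs = pairs, weights = models,
                 center = ctr, scale = scl, cost = cost),
            class = "linear_svm")
}

#' Predict with a linear SVM
#'
#' @param object A \code{\link{svm_train}} model.
#' @param newdata Numeric matrix, observations x features (same columns).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$center))
    stop("feature column mismatch")
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  xa <- cbind(xs, 1)
  k <- length(object$classes)
  votes <- matrix(0, nrow(xa), k, dimnames = list(NULL, object$classes))
  scores <- votes
  for (m in seq_along(object$pairs)) {
    p <- object$pairs[[m]]
    dec <- as.vector(xa %*% object$weights[[m]])
    win <- ifelse(dec >= 0, p[1L], p[2L])
    votes[cbind(seq_along(win), match(win, object$classes))] <-
      votes[cbind(seq_along(win), match(win, object$classes))] + 1
    scores[, p[1L]] <- scores[, p[1L]] + dec
    scores[, p[2L]] <- scores[, p[2L]] - dec
  }
  apply(votes + 1e-9 * scores, 1L, function(v) object$classes[which.max(v)])
}
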
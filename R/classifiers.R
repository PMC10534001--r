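# Feature-branch classifiers: regularised linear discriminant analysis and
# k-nearest neighbours, both operating on z-scored features. Standardisation
# parameters are always estimated on the training data alone and stored in
# the fitted object, so test folds are never touched during fitting.

zscore_fit <- function(x) {
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(centre = centre, scale = scale)
}

zscore_apply <- function(x, z) {
  sweep(sweep(x, 2, z$centre), 2, z$scale, "/")
}

#' Fit a regularised linear discriminant classifier
#'
#' Pooled-covariance LDA with diagonal loading: the pooled within-class
#' covariance gets `ridge * mean(diag(S))` added to its diagonal, which keeps
#' the discriminant well defined when the feature dimension (144 here)
#' exceeds the number of training participants. Features are z-scored using
#' training statistics; class priors are the empirical training proportions.
#'
#' @param x Numeric feature matrix (participants x features).
#' @param y Class labels; exactly two classes, each with at least two
#'   training rows.
#' @param ridge Diagonal-loading factor (default 1e-4).
#' @return Object of class `ppg_lda`.
#' @export
fit_lda <- function(x, y, ridge = 1e-4) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("LDA here is two-class")
  if (any(table(y) < 2)) stop("need at least 2 training rows per class")
  z <- zscore_fit(x)
  xs <- zscore_apply(x, z)
  n <- nrow(xs)
  p <- ncol(xs)
  S <- matrix(0, p, p)
  mu <- matrix(0, 2, p)
  for (ci in 1:2) {
    xc <- xs[y == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(xc)
    S <- S + crossprod(sweep(xc, 2, mu[ci, ]))
  }
  S <- S / (n - 2)
  diag(S) <- diag(S) + ridge * mean(diag(S))
  ch <- chol(S)
  w <- backsolve(ch, forwardsolve(t(ch), t(mu)))   # p x 2, S^-1 mu_c
  const <- -0.5 * colSums(t(mu) * w) + log(table(y)[classes] / n)
  structure(list(classes = classes, zscore = z, w = w,
                 const = as.numeric(const)),
            class = "ppg_lda")
}

#' @export
predict.ppg_lda <- function(object, newdata, ...) {
  xs <- zscore_apply(as.matrix(newdata), object$zscore)
  scores <- sweep(xs %*% object$w, 2, object$const, "+")
  post <- softmax(scores)
  colnames(post) <- object$classes
  list(class = object$classes[max.col(scores, ties.method = "first")],
       posterior = post)
}

#' Fit a k-nearest-neighbour classifier
#'
#' Euclidean distance on z-scored features, majority vote over the `k`
#' nearest training rows; equidistant neighbours are taken in stable
#' training order, and a vote tie is broken in favour of the single nearest
#' neighbour's class.
#'
#' @param x Numeric feature matrix (participants x features).
#' @param y Class labels.
#' @param k Number of neighbours (default 9).
#' @return Object of class `ppg_knn`.
#' @export
fit_knn <- function(x, y, k = 9) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k larger than the training set")
  z <- zscore_fit(x)
  structure(list(x = zscore_apply(x, z), y = as.character(y), k = k,
                 zscore = z),
            class = "ppg_knn")
}

#' @export
predict.ppg_knn <- function(object, newdata, ...) {
  xs <- zscore_apply(as.matrix(newdata), object$zscore)
  k <- object$k
  apply(xs, 1, function(q) {
    d <- sqrt(colSums((t(object$x) - q)^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(object$y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else object$y[nb[1]]
  })
}
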
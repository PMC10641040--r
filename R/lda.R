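## Linear discriminant analysis with pooled within-class covariance.

#' Fit a linear discriminant model
#'
#' Gaussian classifier with one centroid per class and a shared pooled
#' within-class covariance (divisor `n - C`). If the pooled covariance is
#' ill-conditioned (condition number above `cond_threshold`), a ridge of
#' `ridge_scale * trace / p` is added to the diagonal.
#'
#' @param x n x p feature matrix.
#' @param labels class label per row; every class needs >= 2 rows.
#' @param priors `"proportional"` (training frequencies, default) or
#'   `"uniform"`.
#' @param cond_threshold condition number above which the ridge is applied
#'   (default 1e10).
#' @param ridge_scale ridge magnitude relative to `trace / p`
#'   (default 1e-8).
#' @return an [LDAModel-class].
#' @export
fitLDA <- function(x, labels, priors = c("proportional", "uniform"),
                   cond_threshold = 1e10, ridge_scale = 1e-8) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("degenerate problem: all labels identical")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2))
    stop("singular class(es) with one sample: ",
         paste(classes[counts < 2], collapse = ", "),
         "; remove single-specimen classes before fitting")
  p <- ncol(x)
  means <- matrix(0, length(classes), p,
                  dimnames = list(classes, colnames(x)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    rows <- x[labels == cl, , drop = FALSE]
    m <- colMeans(rows)
    means[cl, ] <- m
    Xc <- sweep(rows, 2, m)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(x) - length(classes))
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_threshold) {
    ridge <- ridge_scale * sum(diag(Sw)) / p
    if (ridge <= 0) ridge <- ridge_scale
    Sw <- Sw + diag(ridge, p)
  }
  pri <- switch(priors,
                proportional = as.numeric(counts) / nrow(x),
                uniform = rep(1 / length(classes), length(classes)))
  names(pri) <- classes
  new("LDAModel", classes = classes, means = means, cov = Sw,
      chol = chol(Sw), priors = pri, ridge = ridge)
}

#' Predict class labels and posteriors from an LDA model
#'
#' Posteriors are proportional to
#' `prior * exp(-0.5 * Mahalanobis^2)` under the pooled covariance,
#' normalised per row. The predicted label is the posterior argmax; exact
#' ties go to the lexicographically smallest class label.
#'
#' @param model an [LDAModel-class].
#' @param x n x p feature matrix (p must match the model).
#' @return list with `labels` (character vector) and `posteriors`
#'   (n x C matrix, columns named by class).
#' @export
predictLDA <- function(model, x) {
  stopifnot(is(model, "LDAModel"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(model@means))
    stop("feature dimension mismatch: model has ", ncol(model@means),
         ", input has ", ncol(x))
  C <- length(model@classes)
  logd <- matrix(0, nrow(x), C, dimnames = list(NULL, model@classes))
  for (ci in seq_len(C)) {
    diff <- sweep(x, 2, model@means[ci, ])
    z <- backsolve(model@chol, t(diff), transpose = TRUE)
    logd[, ci] <- log(model@priors[ci]) - 0.5 * colSums(z^2)
  }
  mx <- apply(logd, 1, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)
  ## classes are sorted, so which.max resolves ties lexicographically
  labels <- model@classes[apply(post, 1, which.max)]
  list(labels = labels, posteriors = post)
}
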
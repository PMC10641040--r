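## Superimposition geometry: preshape normalisation, ordinary Procrustes
## alignment, generalized Procrustes analysis, IQR outlier screening.
##
## Internally configurations are held as two n x k matrices (x and y
## coordinates) so that the per-configuration optimal 2D rotation reduces to
## two matrix-vector products:
##   a_i = sum_j x_ij . m_j   (dot products with the consensus)
##   b_i = sum_j x_ij x m_j   (z component of the cross products)
##   theta_i = atan2(b_i, a_i)
## which is the closed-form least-squares rotation without reflection.

.flatten <- function(m) as.vector(t(m))           # (x1,y1,x2,y2,...)
.unflatten <- function(v) matrix(v, ncol = 2, byrow = TRUE)

#' Preshape a landmark configuration
#'
#' Translates the present landmarks to zero centroid and scales to unit
#' centroid size. Centroid size is the square root of the summed squared
#' distances of the landmarks to their centroid, in cm.
#'
#' @param points k x 2 coordinate matrix (only present landmarks).
#' @return list with `points` (normalised k x 2 matrix) and `size`
#'   (centroid size, cm).
#' @export
preshape <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("insufficient landmarks: preshape needs at least 3, got ",
         nrow(points))
  if (any(!is.finite(points))) stop("non-finite coordinates in preshape")
  ctr <- colMeans(points)
  centred <- sweep(points, 2, ctr)
  size <- sqrt(sum(centred^2))
  if (size < 1e-12)
    stop("degenerate configuration: all landmarks coincide")
  list(points = centred / size, size = size)
}

## optimal rotation angle of `source` onto `target` (no reflection)
.optRotation <- function(source, target) {
  a <- sum(source * target)
  b <- sum(source[, 1] * target[, 2] - source[, 2] * target[, 1])
  atan2(b, a)
}

.rotate <- function(points, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * points[, 1] - st * points[, 2],
        st * points[, 1] + ct * points[, 2])
}

#' Ordinary Procrustes alignment of one configuration onto a target
#'
#' Finds the rotation (optionally also a reflection) minimising the summed
#' squared distance between the source and target configurations. Both are
#' expected to be preshaped (centred, unit size); reflection is disallowed
#' by default because sidedness (left- vs right-eyed forms) is a biological
#' signal to preserve.
#'
#' @param target k x 2 reference configuration.
#' @param source k x 2 configuration to rotate.
#' @param allow_reflection also consider the mirrored source and keep the
#'   better fit (default `FALSE`).
#' @return list with `aligned` (rotated source), `angle` (radians),
#'   `reflected` (logical) and `residual` (root summed squared distance).
#' @export
opaAlign <- function(target, source, allow_reflection = FALSE) {
  target <- as.matrix(target); source <- as.matrix(source)
  if (!all(dim(target) == dim(source)))
    stop("dimension mismatch: target is ", nrow(target), " x ",
         ncol(target), ", source is ", nrow(source), " x ", ncol(source))
  theta <- .optRotation(source, target)
  aligned <- .rotate(source, theta)
  res <- sqrt(sum((aligned - target)^2))
  reflected <- FALSE
  if (allow_reflection) {
    mir <- source %*% diag(c(-1, 1))
    theta2 <- .optRotation(mir, target)
    aligned2 <- .rotate(mir, theta2)
    res2 <- sqrt(sum((aligned2 - target)^2))
    if (res2 < res) {
      aligned <- aligned2; theta <- theta2; res <- res2; reflected <- TRUE
    }
  }
  list(aligned = aligned, angle = theta, reflected = reflected,
       residual = res)
}

## Vectorised GPA core on x/y matrices (configurations in rows, already
## preshaped). Returns rotated matrices aligned to the converged consensus.
.gpaCore <- function(Xx, Xy, tol = 1e-10, max_iter = 100L) {
  n <- nrow(Xx)
  ## order-invariant initialisation: normalised mean of the preshapes
  mx <- colMeans(Xx); my <- colMeans(Xy)
  msz <- sqrt(sum(mx^2) + sum(my^2))
  if (msz < 1e-8) { mx <- Xx[1, ]; my <- Xy[1, ]; msz <- 1 }
  mx <- mx / msz; my <- my / msz
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- drop(Xx %*% mx + Xy %*% my)
    b <- drop(Xx %*% my - Xy %*% mx)
    th <- atan2(b, a)
    ct <- cos(th); st <- sin(th)
    Rx <- ct * Xx - st * Xy
    Ry <- st * Xx + ct * Xy
    nx <- colMeans(Rx); ny <- colMeans(Ry)
    nsz <- sqrt(sum(nx^2) + sum(ny^2))
    nx <- nx / nsz; ny <- ny / nsz
    move <- sqrt(mean(c(nx - mx, ny - my)^2))
    mx <- nx; my <- ny
    Xx <- Rx; Xy <- Ry
    if (move < tol) { converged <- TRUE; break }
  }
  ## canonical orientation: first landmark of the consensus on the +x axis
  phi <- atan2(my[1], mx[1])
  ct <- cos(-phi); st <- sin(-phi)
  list(Xx = ct * Xx - st * Xy, Xy = st * Xx + ct * Xy,
       iterations = iter, converged = converged)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a set of complete configurations on a
#' common landmark subset: all configurations are preshaped (centred,
#' scaled to unit centroid size), rotated onto the running consensus, and
#' the consensus re-estimated until it stabilises. The converged ensemble
#' is put in a canonical orientation (consensus landmark 1 on the +x
#' half-axis) so results do not depend on input order or on nuisance
#' rotations of the inputs.
#'
#' @param x a [LandmarkSet-class] (all configurations on one scheme) or a
#'   k x 2 x n array.
#' @param subset landmark indices to analyse (default: all). Every
#'   configuration must be present on the subset.
#' @param tol convergence tolerance on root-mean-square consensus movement
#'   (default 1e-10).
#' @param max_iter iteration cap (default 100); non-convergence returns the
#'   current state with `converged = FALSE` and a warning.
#' @return an [AlignedShapes-class].
#' @export
gpa <- function(x, subset = NULL, tol = 1e-10, max_iter = 100L) {
  if (is(x, "LandmarkSet")) {
    k_all <- vapply(x@coords, nrow, 0L)
    if (length(unique(k_all)) != 1)
      stop("all configurations must share one landmark count; got ",
           paste(unique(k_all), collapse = ", "))
    if (is.null(subset)) subset <- seq_len(k_all[1])
    ok <- vapply(seq_along(x@coords),
                 function(i) all(x@present[[i]][subset]), TRUE)
    if (!all(ok))
      stop("configurations incomplete on the requested subset: ",
           paste(which(!ok), collapse = ", "))
    arr <- vapply(x@coords, function(m) m[subset, , drop = FALSE],
                  matrix(0, length(subset), 2))
    ids <- pairKeys(x)
    info <- x@info
  } else {
    arr <- x
    if (length(dim(arr)) != 3 || dim(arr)[2] != 2)
      stop("expected a k x 2 x n array or a LandmarkSet")
    if (is.null(subset)) subset <- seq_len(dim(arr)[1])
    arr <- arr[subset, , , drop = FALSE]
    ids <- as.character(seq_len(dim(arr)[3]))
    info <- data.frame(row = seq_len(dim(arr)[3]))
  }
  n <- dim(arr)[3]; k <- dim(arr)[1]
  if (n < 2) stop("GPA needs at least 2 configurations")
  Xx <- t(arr[, 1, ]); Xy <- t(arr[, 2, ])
  ## preshape rows
  Xx <- Xx - rowMeans(Xx); Xy <- Xy - rowMeans(Xy)
  sizes <- sqrt(rowSums(Xx^2) + rowSums(Xy^2))
  if (any(sizes < 1e-12)) stop("degenerate configuration (zero size)")
  Xx <- Xx / sizes; Xy <- Xy / sizes
  fit <- .gpaCore(Xx, Xy, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  mx <- colMeans(fit$Xx); my <- colMeans(fit$Xy)
  dists <- sqrt(rowSums(sweep(fit$Xx, 2, mx)^2) +
                rowSums(sweep(fit$Xy, 2, my)^2))
  aligned <- array(0, dim = c(k, 2, n))
  aligned[, 1, ] <- t(fit$Xx)
  aligned[, 2, ] <- t(fit$Xy)
  new("AlignedShapes", aligned = aligned,
      mean_shape = cbind(mx, my, deparse.level = 0),
      centroid_sizes = unname(sizes), distances = unname(dists),
      iterations = fit$iterations, converged = fit$converged,
      subset = as.integer(subset), ids = ids, info = info)
}

#' Flag shape outliers by the interquartile-range rule
#'
#' Flags configurations whose Procrustes distance to the consensus exceeds
#' `Q3 + k * IQR` (strict inequality; one-sided, large distances only).
#' Flags are returned, not applied: the caller decides on removal.
#'
#' @param aligned an [AlignedShapes-class] (>= 4 configurations), or a
#'   numeric vector of distances.
#' @param k IQR multiplier (default 1.5).
#' @return logical vector of flags.
#' @export
flagOutliers <- function(aligned, k = 1.5) {
  d <- if (is(aligned, "AlignedShapes")) aligned@distances else aligned
  if (length(d) < 4)
    stop("outlier screening needs at least 4 configurations")
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  d > q[2] + k * (q[2] - q[1])
}
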
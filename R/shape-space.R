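## PCA of aligned shapes, projection, combined-view fusion, shape
## reconstruction along axes, and variance accounting.
##
## PCA operates on the aligned coordinates as first-order tangent
## coordinates about the consensus (no separate orthogonal projection);
## shape variation in this material is small enough for the linear
## approximation. Eigenvalues use the divisor n, so their sum equals the
## mean squared deviation of the flattened coordinates from the consensus.

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened aligned
#' coordinates about the consensus. All axes with eigenvalue above
#' `1e-12 * trace` (numerical rank) are retained. Axis signs follow the
#' convention that each axis' largest-magnitude loading is positive.
#'
#' @param aligned an [AlignedShapes-class] with at least 3 configurations.
#' @return a [ShapeSpace-class].
#' @export
fitShapePCA <- function(aligned) {
  stopifnot(is(aligned, "AlignedShapes"))
  n <- dim(aligned@aligned)[3]
  if (n < 3) stop("PCA needs at least 3 configurations")
  X <- t(apply(aligned@aligned, 3, .flatten))
  centre <- .flatten(aligned@mean_shape)
  Xc <- sweep(X, 2, centre)
  sv <- svd(Xc)
  eig <- sv$d^2 / n
  total <- sum(eig)
  keep <- which(eig > 1e-12 * total)
  axes <- sv$v[, keep, drop = FALSE]
  eig <- eig[keep]
  ## sign convention: largest-magnitude loading positive
  for (j in seq_along(keep)) {
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- Xc %*% axes
  rownames(scores) <- aligned@ids
  colnames(scores) <- paste0("PC", seq_along(keep))
  new("ShapeSpace", mean_shape = aligned@mean_shape, axes = axes,
      eigenvalues = eig, scores = scores,
      pct_variance = 100 * eig / total, info = aligned@info)
}

#' Project aligned configurations into a shape space
#'
#' Configurations must already be superimposed onto `meanShape(space)` on
#' the same landmark subset (see [standardizeAndScore()] for the full
#' test-set pipeline).
#'
#' @param space a [ShapeSpace-class].
#' @param configs a k x 2 matrix, a list of such matrices, or a k x 2 x n
#'   array.
#' @return score matrix (one row per configuration).
#' @export
projectShapes <- function(space, configs) {
  stopifnot(is(space, "ShapeSpace"))
  if (is.list(configs)) configs <- simplify2array(configs)
  if (length(dim(configs)) == 2) configs <- array(configs,
                                                 c(dim(configs), 1))
  k <- nrow(space@mean_shape)
  if (dim(configs)[1] != k)
    stop("landmark count mismatch: space has ", k, ", configurations have ",
         dim(configs)[1])
  X <- t(apply(configs, 3, .flatten))
  sweep(X, 2, .flatten(space@mean_shape)) %*% space@axes
}

#' Combine per-view PC scores for shared vertebrae
#'
#' Inner join of the per-view score matrices on the vertebra pair key;
#' score blocks are concatenated column-wise, unweighted. Vertebrae missing
#' from any view are dropped and reported.
#'
#' @param spaces named list of [ShapeSpace-class] objects (names = views),
#'   or a named list of score matrices with rownames as keys.
#' @return a [CombinedScores-class].
#' @export
combineViews <- function(spaces) {
  stopifnot(length(spaces) >= 1, !is.null(names(spaces)))
  mats <- lapply(spaces, function(s)
    if (is(s, "ShapeSpace")) s@scores else as.matrix(s))
  ids <- Reduce(intersect, lapply(mats, rownames))
  if (!length(ids)) stop("no vertebrae shared across the views")
  all_ids <- unique(unlist(lapply(mats, rownames)))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped))
    message("combineViews: dropped ", length(dropped),
            " vertebra(e) missing a view: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  blocks <- rep(names(mats), vapply(mats, ncol, 0L))
  scores <- do.call(cbind, lapply(mats, function(m) m[ids, , drop = FALSE]))
  rownames(scores) <- ids
  info <- data.frame(id = ids, stringsAsFactors = FALSE)
  first <- spaces[[1]]
  if (is(first, "ShapeSpace") && nrow(first@info)) {
    m <- match(ids, rownames(first@scores))
    info <- first@info[m, , drop = FALSE]
    rownames(info) <- NULL
  }
  new("CombinedScores", scores = scores, blocks = blocks, info = info,
      dropped = as.character(dropped))
}

#' Reconstruct the shape at a position along a PC axis
#'
#' Returns `mean_shape + s * axis_k` as a landmark configuration; with
#' `s` at the observed score extremes this gives the deformation endpoints
#' used to visualise shape variation along an axis.
#'
#' @param space a [ShapeSpace-class].
#' @param axis axis number (within the retained axes).
#' @param score position along the axis.
#' @return k x 2 coordinate matrix.
#' @export
shapeAlongAxis <- function(space, axis, score) {
  stopifnot(is(space, "ShapeSpace"))
  if (axis < 1 || axis > ncol(space@axes))
    stop("axis ", axis, " out of range (", ncol(space@axes),
         " axes retained)")
  .unflatten(.flatten(space@mean_shape) + score * space@axes[, axis])
}

#' Per-axis percentage of variance
#'
#' @param space a [ShapeSpace-class].
#' @param n_axes number of leading axes to report (default 3, as
#'   conventional for shape-variation tables).
#' @return data.frame with `axis`, `pct_variance`, `cumulative`.
#' @export
varianceTable <- function(space, n_axes = 3) {
  stopifnot(is(space, "ShapeSpace"))
  n_axes <- min(n_axes, length(space@pct_variance))
  pct <- space@pct_variance[seq_len(n_axes)]
  data.frame(axis = paste0("PC", seq_len(n_axes)), pct_variance = pct,
             cumulative = cumsum(pct))
}

## Second-stage PCA on a score table (centred, unscaled). Used to condense
## (combined) PC scores before LDA and for combined-view reconstruction.
.fitSecondPCA <- function(scores, cum_var = 0.99, cap = Inf) {
  centre <- colMeans(scores)
  Xc <- sweep(scores, 2, centre)
  sv <- svd(Xc)
  eig <- sv$d^2 / nrow(scores)
  keep <- which(eig > 1e-12 * max(sum(eig), 1e-300))
  cumfrac <- cumsum(eig[keep]) / sum(eig[keep])
  ndim <- which(cumfrac >= cum_var - 1e-12)[1]
  if (is.na(ndim)) ndim <- length(keep)
  ndim <- min(ndim, length(keep))
  if (is.finite(cap)) ndim <- min(ndim, as.integer(cap))
  ndim <- max(1L, ndim)
  list(centre = centre, rotation = sv$v[, seq_len(ndim), drop = FALSE],
       ndim = ndim, eigenvalues = eig[seq_len(ndim)])
}

.applySecondPCA <- function(fit, scores) {
  sweep(scores, 2, fit$centre) %*% fit$rotation
}

#' Reconstruct per-view shapes along a combined-view axis
#'
#' For an axis of a second-stage PCA fitted on combined per-view scores,
#' maps a position `s` on that axis back through each view's score block
#' and PC basis, giving one reconstructed configuration per view.
#'
#' @param spaces named list of per-view [ShapeSpace-class] objects.
#' @param combined the [CombinedScores-class] the second PCA was fitted on.
#' @param fit2 second-PCA fit as returned by the classifier (list with
#'   `centre`, `rotation`).
#' @param axis combined-axis number.
#' @param score position along the axis.
#' @return named list of k x 2 matrices, one per view.
#' @export
combinedShapeAlongAxis <- function(spaces, combined, fit2, axis, score) {
  v <- fit2$centre + score * fit2$rotation[, axis]
  out <- list()
  for (view in names(spaces)) {
    block <- which(combined@blocks == view)
    sp <- spaces[[view]]
    out[[view]] <- .unflatten(.flatten(sp@mean_shape) +
                              as.vector(sp@axes %*% v[block]))
  }
  out
}
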
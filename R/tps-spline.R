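## Thin-plate spline interpolation and missing-landmark estimation.

## TPS kernel U(r) = r^2 log(r^2); U(0) = 0.
.tpsKernel <- function(r2) ifelse(r2 <= 0, 0, r2 * log(r2))

.tpsSystem <- function(source) {
  k <- nrow(source)
  d2 <- as.matrix(dist(source))^2
  K <- .tpsKernel(d2)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  L
}

#' Thin-plate spline interpolation
#'
#' Fits the standard 2D thin-plate spline (kernel `U(r) = r^2 log r^2` plus
#' an affine part) interpolating `source -> target` exactly, and applies it
#' to query points. The interpolant reproduces affine maps with zero
#' bending energy, which is the basis of missing-landmark estimation.
#'
#' @param source k x 2 source landmarks (>= 3, not collinear).
#' @param target k x 2 target landmarks.
#' @param query q x 2 points to map.
#' @return q x 2 matrix of mapped points.
#' @export
tpsInterpolate <- function(source, target, query) {
  source <- as.matrix(source); target <- as.matrix(target)
  query <- as.matrix(query)
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of landmarks")
  k <- nrow(source)
  if (k < 3) stop("thin-plate spline needs at least 3 source landmarks")
  L <- .tpsSystem(source)
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate-spline system: collinear or duplicated ",
         "source landmarks"))
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[k + 1:3, , drop = FALSE]
  ## kernel distances query -> source
  d2 <- outer(rowSums(query^2), rowSums(source^2), "+") -
    2 * tcrossprod(query, source)
  d2[d2 < 0] <- 0
  U <- .tpsKernel(d2)
  cbind(1, query) %*% a + U %*% w
}

## exact affine map through >= 3 points (least squares if over-determined)
.affineMap <- function(source, target, query) {
  A <- cbind(1, source)
  beta <- qr.solve(A, target)
  cbind(1, query) %*% beta
}

.collinear <- function(points, tol = 1e-9) {
  ctr <- sweep(as.matrix(points), 2, colMeans(points))
  s <- svd(ctr, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1e-300)
}

#' Estimate missing landmarks from the complete-specimen consensus
#'
#' For each incomplete configuration, the consensus (Procrustes mean) of
#' the complete configurations is warped onto the incomplete configuration
#' by a thin-plate spline through the shared present landmarks, and the
#' missing positions are filled from the warped consensus. Complete
#' configurations pass through untouched; filled landmarks are flagged in
#' the `estimated` mask. With exactly 3 shared landmarks the warp is the
#' (exact) affine map, flagged `affine_fill`.
#'
#' @param x a [LandmarkSet-class]; all configurations on one scheme.
#' @param min_present minimum present, non-collinear landmarks an
#'   incomplete configuration needs (default 4); configurations below the
#'   minimum are left untouched and reported via a warning.
#' @return the completed [LandmarkSet-class].
#' @export
estimateMissing <- function(x, min_present = 4) {
  stopifnot(is(x, "LandmarkSet"))
  k_all <- vapply(x@coords, nrow, 0L)
  if (length(unique(k_all)) > 1)
    stop("all configurations must share one landmark count")
  complete <- vapply(x@present, all, TRUE)
  if (all(complete)) return(x)
  if (sum(complete) < 2)
    stop("cannot estimate: fewer than 2 complete configurations")
  consensus <- meanShape(gpa(x[complete]))
  skipped <- integer(0)
  for (i in which(!complete)) {
    shared <- which(x@present[[i]])
    if (length(shared) < min_present || .collinear(consensus[shared, ])) {
      if (length(shared) < 3 || .collinear(consensus[shared, ])) {
        skipped <- c(skipped, i)
        next
      }
      ## exactly 3 non-collinear: purely affine fill
      filled <- .affineMap(consensus[shared, , drop = FALSE],
                           x@coords[[i]][shared, , drop = FALSE],
                           consensus[-shared, , drop = FALSE])
    } else {
      filled <- tpsInterpolate(consensus[shared, , drop = FALSE],
                               x@coords[[i]][shared, , drop = FALSE],
                               consensus[-shared, , drop = FALSE])
    }
    gap <- setdiff(seq_len(nrow(consensus)), shared)
    x@coords[[i]][gap, ] <- filled
    x@present[[i]][gap] <- TRUE
    x@estimated[[i]][gap] <- TRUE
  }
  if (length(skipped))
    warning("configurations below min_present left incomplete: ",
            paste(skipped, collapse = ", "))
  x
}
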
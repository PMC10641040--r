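## Generics and simple methods (accessors, show, subsetting).

#' @describeIn LandmarkSet-class number of configurations
#' @param x a `LandmarkSet`.
#' @export
setMethod("length", "LandmarkSet", function(x) length(x@coords))

#' Coordinates of the configurations
#' @param x a [LandmarkSet-class].
#' @return list of k x 2 matrices.
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @rdname landmarkCoords
#' @export
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' Presence masks
#' @param x a [LandmarkSet-class].
#' @return list of logical vectors.
#' @export
setGeneric("presentMask", function(x) standardGeneric("presentMask"))

#' @rdname presentMask
#' @export
setMethod("presentMask", "LandmarkSet", function(x) x@present)

#' Imputation masks
#' @param x a [LandmarkSet-class].
#' @export
setGeneric("estimatedMask", function(x) standardGeneric("estimatedMask"))

#' @rdname estimatedMask
#' @export
setMethod("estimatedMask", "LandmarkSet", function(x) x@estimated)

#' Per-configuration metadata
#' @param x a flatmorph container.
#' @export
setGeneric("specimenInfo", function(x) standardGeneric("specimenInfo"))

#' @rdname specimenInfo
#' @export
setMethod("specimenInfo", "LandmarkSet", function(x) x@info)

#' @rdname specimenInfo
#' @export
setMethod("specimenInfo", "AlignedShapes", function(x) x@info)

#' @rdname specimenInfo
#' @export
setMethod("specimenInfo", "ShapeSpace", function(x) x@info)

#' Vertebra pair keys
#'
#' A key identifying the physical vertebra a configuration belongs to
#' (`sample_id|vertebra_type`); the two views of one vertebra share a key.
#' @param x a [LandmarkSet-class].
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname pairKeys
#' @export
setMethod("pairKeys", "LandmarkSet", function(x)
  paste(x@info$sample_id, x@info$vertebra, sep = "|"))

#' @describeIn LandmarkSet-class subset configurations
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LandmarkSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("LandmarkSet", coords = x@coords[i], present = x@present[i],
      estimated = x@estimated[i], info = x@info[i, , drop = FALSE])
})

#' Concatenate landmark sets
#' @param x,... `LandmarkSet` objects.
#' @export
setMethod("c", "LandmarkSet", function(x, ...) {
  rest <- list(...)
  coords <- x@coords; present <- x@present
  estimated <- x@estimated; info <- x@info
  for (y in rest) {
    coords <- c(coords, y@coords)
    present <- c(present, y@present)
    estimated <- c(estimated, y@estimated)
    info <- rbind(info, y@info)
  }
  rownames(info) <- NULL
  new("LandmarkSet", coords = coords, present = present,
      estimated = estimated, info = info)
})

#' Subset a LandmarkSet by view and/or vertebra type
#' @param x a [LandmarkSet-class].
#' @param view optional view to keep.
#' @param vertebra optional vertebra type(s) to keep.
#' @export
subsetConfigs <- function(x, view = NULL, vertebra = NULL) {
  keep <- rep(TRUE, length(x))
  if (!is.null(view)) keep <- keep & x@info$view == view
  if (!is.null(vertebra)) keep <- keep & x@info$vertebra %in% vertebra
  x[keep]
}

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet with", length(object), "configurations\n")
  if (length(object)) {
    cat("  views:    ", paste(names(table(object@info$view)),
        table(object@info$view), collapse = ", "), "\n")
    cat("  vertebrae:", paste(names(table(object@info$vertebra)),
        table(object@info$vertebra), collapse = ", "), "\n")
    npres <- vapply(object@present, sum, 0L)
    cat("  landmarks present: ", min(npres), "-", max(npres), "\n", sep = "")
  }
})

#' Aligned coordinates
#' @param x an [AlignedShapes-class].
#' @return k x 2 x n array.
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))

#' @rdname alignedCoords
#' @export
setMethod("alignedCoords", "AlignedShapes", function(x) x@aligned)

#' Consensus (mean) shape
#' @param x an [AlignedShapes-class] or [ShapeSpace-class].
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))

#' @rdname meanShape
#' @export
setMethod("meanShape", "AlignedShapes", function(x) x@mean_shape)

#' @rdname meanShape
#' @export
setMethod("meanShape", "ShapeSpace", function(x) x@mean_shape)

#' Centroid sizes (cm)
#' @param x an [AlignedShapes-class].
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))

#' @rdname centroidSizes
#' @export
setMethod("centroidSizes", "AlignedShapes", function(x) x@centroid_sizes)

#' Procrustes distances to the consensus
#' @param x an [AlignedShapes-class].
#' @export
setGeneric("procrustesDistances",
           function(x) standardGeneric("procrustesDistances"))

#' @rdname procrustesDistances
#' @export
setMethod("procrustesDistances", "AlignedShapes", function(x) x@distances)

setMethod("show", "AlignedShapes", function(object) {
  d <- dim(object@aligned)
  cat("AlignedShapes:", d[3], "configurations,", d[1], "landmarks\n")
  cat("  GPA iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  Procrustes distance range: ",
      sprintf("%.4g - %.4g", min(object@distances), max(object@distances)),
      "\n", sep = "")
})

#' PC scores
#' @param x a [ShapeSpace-class] or [CombinedScores-class].
#' @export
setGeneric("shapeScores", function(x) standardGeneric("shapeScores"))

#' @rdname shapeScores
#' @export
setMethod("shapeScores", "ShapeSpace", function(x) x@scores)

#' @rdname shapeScores
#' @export
setMethod("shapeScores", "CombinedScores", function(x) x@scores)

#' Percentage of variance per axis
#' @param x a [ShapeSpace-class].
#' @export
setGeneric("pctVariance", function(x) standardGeneric("pctVariance"))

#' @rdname pctVariance
#' @export
setMethod("pctVariance", "ShapeSpace", function(x) x@pct_variance)

setMethod("show", "ShapeSpace", function(object) {
  cat("ShapeSpace:", nrow(object@scores), "configurations,",
      ncol(object@axes), "axes\n")
  k <- min(3, length(object@pct_variance))
  cat("  % variance (first axes):",
      paste(sprintf("%.2f", object@pct_variance[seq_len(k)]),
            collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", object@level, "level,",
      paste(object@views, collapse = "+"), "view(s)\n")
  cat(sprintf("  accuracy %.4f +/- %.2f over %d reps (%.0f:%.0f split)\n",
              object@mean, object@sd, object@reps,
              100 * object@train_fraction, 100 * (1 - object@train_fraction)))
})

setMethod("show", "IdentificationResult", function(object) {
  cat("IdentificationResult for", object@sample_id,
      sprintf("(%s)\n", object@mode))
  for (i in seq_len(nrow(object@decisions)))
    cat(sprintf("  %-13s -> %-12s posterior %.3f\n",
                object@decisions$level[i], object@decisions$label[i],
                object@decisions$posterior[i]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "VertebraClassifier", function(object) {
  cat("VertebraClassifier:", object@level, "level,",
      paste(object@views, collapse = "+"), "view(s),",
      nrow(object@classes), "classes\n")
})
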
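## S4 classes for the containers moving through the pipeline.

#' LandmarkSet: a collection of 2D landmark configurations
#'
#' The central data container: one element per digitised configuration (one
#' view of one vertebra). Coordinates are stored in cm (after application of
#' the TPS SCALE factor); a presence mask records missing landmarks; a
#' parallel mask records landmarks filled in by [estimateMissing()].
#'
#' @slot coords list of k x 2 numeric matrices (x, y in cm).
#' @slot present list of logical vectors, one flag per landmark.
#' @slot estimated list of logical vectors flagging imputed landmarks.
#' @slot info data.frame with one row per configuration: `order`,
#'   `sample_id`, `vertebra`, `view`, `family`, `genus`, `species`,
#'   `provenance`, `form` (`"normal"` or `"mirror"`), `scale`, `scaled`.
#' @export
setClass("LandmarkSet", representation(
  coords = "list", present = "list", estimated = "list",
  info = "data.frame"))

.INFO_COLS <- c("order", "sample_id", "vertebra", "view", "family",
                "genus", "species", "provenance", "form", "scale", "scaled")

setValidity("LandmarkSet", function(object) {
  n <- length(object@coords)
  if (length(object@present) != n || length(object@estimated) != n)
    return("coords, present and estimated must have equal length")
  if (nrow(object@info) != n)
    return("info must have one row per configuration")
  miss <- setdiff(.INFO_COLS, names(object@info))
  if (length(miss))
    return(paste("info lacks columns:", paste(miss, collapse = ", ")))
  for (i in seq_len(n)) {
    xy <- object@coords[[i]]
    if (!is.matrix(xy) || ncol(xy) != 2 || !is.numeric(xy))
      return(sprintf("coords[[%d]] is not a numeric k x 2 matrix", i))
    if (length(object@present[[i]]) != nrow(xy))
      return(sprintf("present[[%d]] length mismatch", i))
    if (any(!is.finite(xy[object@present[[i]], , drop = FALSE])))
      return(sprintf("non-finite coordinates flagged present in record %d", i))
  }
  if (!all(object@info$vertebra %in% .VERTEBRA_TYPES))
    return("info$vertebra contains values outside the vertebra-type enum")
  if (!all(object@info$view %in% .VIEWS))
    return("info$view contains values outside the view enum")
  if (any(!nzchar(object@info$sample_id)))
    return("empty sample_id")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param coords list of k x 2 numeric matrices (cm).
#' @param info data.frame of per-configuration metadata; missing columns are
#'   filled with defaults (`provenance = "modern"`, `form = "normal"`,
#'   `scale = 1`, `scaled = TRUE`, `order` = running number).
#' @param present optional list of logical masks (default: all present).
#' @param estimated optional list of logical masks (default: none).
#' @return a [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(coords, info, present = NULL, estimated = NULL) {
  n <- length(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  if (is.null(present))
    present <- lapply(coords, function(m) rep(TRUE, nrow(m)))
  if (is.null(estimated))
    estimated <- lapply(coords, function(m) rep(FALSE, nrow(m)))
  defaults <- list(order = seq_len(n), provenance = "modern",
                   form = "normal", scale = 1, scaled = TRUE,
                   family = "UNK", genus = "UNK", species = "UNK")
  for (col in names(defaults))
    if (is.null(info[[col]]))
      info[[col]] <- rep(defaults[[col]], length.out = n)
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  rownames(info) <- NULL
  new("LandmarkSet", coords = coords, present = present,
      estimated = estimated, info = info[, .INFO_COLS, drop = FALSE])
}

#' AlignedShapes: output of generalized Procrustes analysis
#'
#' @slot aligned k x 2 x n array of superimposed coordinates.
#' @slot mean_shape k x 2 consensus configuration (arithmetic mean of the
#'   aligned configurations).
#' @slot centroid_sizes per-configuration centroid size in cm.
#' @slot distances per-configuration Procrustes distance to the consensus.
#' @slot iterations number of GPA iterations run.
#' @slot converged whether the consensus stabilised within tolerance.
#' @slot subset landmark indices (into the source configurations) used.
#' @slot ids per-configuration identifiers (vertebra pair keys).
#' @slot info metadata carried through from the source [LandmarkSet-class].
#' @export
setClass("AlignedShapes", representation(
  aligned = "array", mean_shape = "matrix", centroid_sizes = "numeric",
  distances = "numeric", iterations = "integer", converged = "logical",
  subset = "integer", ids = "character", info = "data.frame"))

setValidity("AlignedShapes", function(object) {
  d <- dim(object@aligned)
  if (length(d) != 3 || d[2] != 2)
    return("aligned must be a k x 2 x n array")
  n <- d[3]
  if (length(object@centroid_sizes) != n || length(object@distances) != n)
    return("centroid_sizes/distances length mismatch")
  if (any(object@distances < 0)) return("negative Procrustes distance")
  if (!all(dim(object@mean_shape) == d[1:2]))
    return("mean_shape dimension mismatch")
  TRUE
})

#' ShapeSpace: PCA of aligned shapes
#'
#' @slot mean_shape consensus configuration the space is centred on.
#' @slot axes 2k x m matrix of orthonormal loading vectors over flattened
#'   (x1, y1, x2, y2, ...) coordinates.
#' @slot eigenvalues non-negative variances along the axes, descending.
#' @slot scores n x m matrix of configuration scores (rownames = ids).
#' @slot pct_variance percentage of total variance per axis.
#' @slot info per-configuration metadata (rows match scores).
#' @export
setClass("ShapeSpace", representation(
  mean_shape = "matrix", axes = "matrix", eigenvalues = "numeric",
  scores = "matrix", pct_variance = "numeric", info = "data.frame"))

setValidity("ShapeSpace", function(object) {
  m <- ncol(object@axes)
  if (length(object@eigenvalues) != m || ncol(object@scores) != m)
    return("axes/eigenvalues/scores dimension mismatch")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be descending")
  if (m > 1) {
    g <- crossprod(object@axes)
    if (max(abs(g - diag(m))) > 1e-6)
      return("axes are not orthonormal")
  }
  TRUE
})

#' CombinedScores: fused per-view PC scores
#'
#' @slot scores n x p matrix; rows are vertebrae present in every view,
#'   columns are the concatenated per-view PC scores.
#' @slot blocks character vector, one entry per column, naming the view the
#'   column came from.
#' @slot info per-row metadata.
#' @slot dropped ids of vertebrae excluded for missing a view.
#' @export
setClass("CombinedScores", representation(
  scores = "matrix", blocks = "character", info = "data.frame",
  dropped = "character"))

#' LDAModel: linear discriminant analysis with pooled covariance
#'
#' @slot classes sorted class labels.
#' @slot means class centroid per row, in feature space.
#' @slot cov pooled within-class covariance (after any ridging).
#' @slot chol upper-triangular Cholesky factor of `cov`.
#' @slot priors per-class prior probabilities (sum to 1).
#' @slot ridge ridge added to the covariance diagonal (0 if none).
#' @export
setClass("LDAModel", representation(
  classes = "character", means = "matrix", cov = "matrix",
  chol = "matrix", priors = "numeric", ridge = "numeric"))

setValidity("LDAModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-10 || any(object@priors <= 0))
    return("priors must be positive and sum to 1")
  if (nrow(object@means) != length(object@classes))
    return("one centroid per class required")
  TRUE
})

#' VertebraClassifier: frozen two-stage PCA-LDA training pipeline
#'
#' All statistics are estimated on the training set and frozen: per-view GPA
#' mean shape and PC basis, the second-stage PCA centre/rotation, and the
#' LDA parameters. Test material is standardised against these, never
#' re-estimated.
#'
#' @slot level `"vertebra_type"`, `"family"`, `"species"` or `"sidedness"`.
#' @slot views views used, in block order.
#' @slot subsets per-view landmark index subset.
#' @slot mean_shapes per-view training consensus configuration.
#' @slot bases per-view PC loading matrix.
#' @slot centre2 second-PCA centring vector.
#' @slot rot2 second-PCA rotation (columns = retained axes).
#' @slot lda fitted [LDAModel-class].
#' @slot classes data.frame of training class sizes.
#' @export
setClass("VertebraClassifier", representation(
  level = "character", views = "character", subsets = "list",
  mean_shapes = "list", bases = "list", centre2 = "numeric",
  rot2 = "matrix", lda = "LDAModel", classes = "data.frame"))

#' EvaluationReport: bootstrap classification accuracy
#'
#' @slot accuracies per-repetition test-set accuracy.
#' @slot mean,sd summary over repetitions.
#' @slot confusion pooled confusion counts (true x predicted).
#' @slot reps number of repetitions.
#' @slot train_fraction training share of each split.
#' @slot seed RNG seed the evaluation ran under.
#' @slot level,views what was classified and with which views.
#' @export
setClass("EvaluationReport", representation(
  accuracies = "numeric", mean = "numeric", sd = "numeric",
  confusion = "matrix", reps = "integer", train_fraction = "numeric",
  seed = "integer", level = "character", views = "character"))

setValidity("EvaluationReport", function(object) {
  if (any(object@accuracies < 0 | object@accuracies > 1))
    return("accuracies must lie in [0, 1]")
  if (abs(object@mean - mean(object@accuracies)) > 1e-12)
    return("stored mean inconsistent with per-rep accuracies")
  TRUE
})

#' IdentificationResult: per-sample hierarchical identification
#'
#' @slot sample_id identifier of the vertebra identified.
#' @slot mode `"full_chain"` (type, then family, then species) or
#'   `"given_type"` (type known from visual inspection).
#' @slot decisions data.frame with columns `level`, `label`, `posterior`.
#' @slot views_used views that contributed at the final level.
#' @slot landmarks_used per-view landmark indices actually analysed.
#' @slot flags diagnostic flags (e.g. `"single_view_only"`).
#' @slot chained_posterior product of the per-level winning posteriors.
#' @export
setClass("IdentificationResult", representation(
  sample_id = "character", mode = "character", decisions = "data.frame",
  views_used = "character", landmarks_used = "list", flags = "character",
  chained_posterior = "numeric"))

#' SyntheticSpec: study-condition parameters for the landmark generator
#'
#' Defaults emulate the scale and structure of a modern two-view flatfish
#' vertebra reference collection: 19 taxa in 5 families, 73 specimens with
#' the collection's per-taxon counts, ~10 vertebrae photographed per
#' specimen, mirror (left-eyed) forms in the largest taxon, and
#' digitisation nuisance in rotation, translation and scale.
#'
#' @slot taxa_per_family named integer: taxa per family.
#' @slot specimens_per_taxon integer: specimens per taxon (recycled).
#' @slot types vertebra types generated.
#' @slot n_atlas atlas vertebrae per specimen (if `"atlas"` in `types`).
#' @slot n_per_type vertebrae per non-atlas type per specimen.
#' @slot separation between-taxon mean-shape distance in units of
#'   `within_sd`.
#' @slot within_sd isotropic per-landmark coordinate SD (shape units of a
#'   unit-centroid-size template).
#' @slot type_effect between-vertebra-type mean-shape distance in units of
#'   `within_sd`.
#' @slot mirror_fraction fraction of the mirror taxon's specimens generated
#'   as mirror forms.
#' @slot mirror_taxon index of the taxon carrying mirror forms.
#' @slot rotation_range,translation_range,scale_range,digitisation_range
#'   nuisance ranges (uniform): rotation (rad), translation (cm), physical
#'   size factor, digitiser units per cm.
#' @slot structural_missing whether cervical configurations mark the
#'   structurally absent landmarks as missing.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec", representation(
  taxa_per_family = "integer", specimens_per_taxon = "integer",
  types = "character", n_atlas = "integer", n_per_type = "integer",
  separation = "numeric", within_sd = "numeric", type_effect = "numeric",
  mirror_fraction = "numeric", mirror_taxon = "integer",
  rotation_range = "numeric", translation_range = "numeric",
  scale_range = "numeric", digitisation_range = "numeric",
  structural_missing = "logical", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (any(object@taxa_per_family < 1) || any(object@specimens_per_taxon < 1))
    return("taxa and specimen counts must be positive")
  if (object@separation < 0 || object@within_sd < 0 || object@type_effect < 0)
    return("separation, within_sd and type_effect must be non-negative")
  if (object@mirror_fraction < 0 || object@mirror_fraction > 1)
    return("mirror_fraction must lie in [0, 1]")
  if (!all(object@types %in% .VERTEBRA_TYPES))
    return("types outside the vertebra-type enum")
  TRUE
})
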
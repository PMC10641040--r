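## Two-stage PCA-LDA classification of vertebrae, with frozen test-set
## standardisation, bootstrap accuracy evaluation, and hierarchical
## accuracy chaining.

.levelLabels <- function(info, level) {
  switch(level,
         vertebra_type = info$vertebra,
         family = info$family,
         species = info$species,
         sidedness = info$form,
         stop("unknown level: ", level))
}

.defaultSubset <- function(view, types, level) {
  types <- unique(types)
  if (identical(level, "vertebra_type"))
    return(landmarkScheme(view, "precaudal")$shared)
  if (length(types) == 1)
    return(analysisSubset(view, types, level))
  if ("atlas" %in% types)
    stop("atlas vertebrae cannot be mixed with other types in one analysis")
  ## mixed non-atlas types: landmarks usable in every type present
  Reduce(intersect, lapply(types, function(t) analysisSubset(view, t, level)))
}

#' Train a two-stage PCA-LDA vertebra classifier
#'
#' Per view: GPA on the analysis landmark subset, then PCA. The per-view
#' PC scores are fused by concatenation ([combineViews()]), condensed by a
#' second, centred (unscaled) PCA, and classified by LDA on the retained
#' second-stage scores. Classes with a single vertebra are removed before
#' training. All training statistics (mean shapes, PC bases, second-PCA
#' rotation, LDA parameters) are frozen in the returned model.
#'
#' @param x a [LandmarkSet-class] holding the training configurations for
#'   all requested views (complete on the analysis subset; run
#'   [estimateMissing()] first if needed).
#' @param level `"vertebra_type"`, `"family"`, `"species"` or
#'   `"sidedness"`.
#' @param views views to use, in block order (default both).
#' @param subsets optional named list of per-view landmark subsets;
#'   defaults follow [analysisSubset()] for the data's vertebra types.
#' @param cum_var cumulative-variance retention for the second PCA
#'   (default 0.99); the dimension is additionally capped at
#'   `n_train - n_classes` to keep the pooled covariance invertible.
#' @param priors prior mode passed to [fitLDA()].
#' @return a [VertebraClassifier-class].
#' @export
trainClassifier <- function(x, level, views = c("anterior", "sinistral"),
                            subsets = NULL, cum_var = 0.99,
                            priors = "proportional") {
  stopifnot(is(x, "LandmarkSet"))
  per_view <- lapply(views, function(v) subsetConfigs(x, view = v))
  names(per_view) <- views
  for (v in views)
    if (!length(per_view[[v]])) stop("no configurations for view ", v)
  ids <- Reduce(intersect, lapply(per_view, pairKeys))
  if (!length(ids)) stop("no vertebrae present in all requested views")
  ## class filtering on paired vertebrae
  ref <- per_view[[1]][match(ids, pairKeys(per_view[[1]]))]
  labels <- .levelLabels(ref@info, level)
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    message("removing single-vertebra class(es): ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    ids <- ids[keep]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2)
    stop("fewer than 2 classes with >= 2 vertebrae at level ", level)
  spaces <- list(); mean_shapes <- list(); bases <- list()
  use_subsets <- list()
  for (v in views) {
    lv <- per_view[[v]][match(ids, pairKeys(per_view[[v]]))]
    sub <- if (!is.null(subsets)) subsets[[v]]
           else .defaultSubset(v, lv@info$vertebra, level)
    al <- gpa(lv, subset = sub)
    sp <- fitShapePCA(al)
    spaces[[v]] <- sp
    mean_shapes[[v]] <- sp@mean_shape
    bases[[v]] <- sp@axes
    use_subsets[[v]] <- sub
  }
  comb <- combineViews(spaces)
  stopifnot(identical(rownames(comb@scores), ids))
  cap <- length(ids) - length(unique(labels))
  fit2 <- .fitSecondPCA(comb@scores, cum_var = cum_var, cap = cap)
  z <- .applySecondPCA(fit2, comb@scores)
  lda <- fitLDA(z, labels, priors = priors)
  cls <- as.data.frame(table(labels), stringsAsFactors = FALSE)
  names(cls) <- c("class", "n")
  new("VertebraClassifier", level = level, views = views,
      subsets = use_subsets, mean_shapes = mean_shapes, bases = bases,
      centre2 = fit2$centre, rot2 = fit2$rotation, lda = lda,
      classes = cls)
}

#' Standardise test configurations against a trained classifier
#'
#' Each test configuration is preshaped and rotated ([opaAlign()], no
#' reflection) onto the view's frozen training mean shape, projected on the
#' frozen training PC basis, the view blocks are concatenated, and the
#' frozen second-PCA rotation applied. Training statistics are never
#' recomputed from test material.
#'
#' @param model a [VertebraClassifier-class].
#' @param x a [LandmarkSet-class] of test configurations.
#' @return matrix of second-stage scores, rownames = vertebra pair keys.
#' @export
standardizeAndScore <- function(model, x) {
  stopifnot(is(model, "VertebraClassifier"), is(x, "LandmarkSet"))
  block_scores <- list()
  for (v in model@views) {
    lv <- subsetConfigs(x, view = v)
    sub <- model@subsets[[v]]
    sc <- matrix(0, length(lv), ncol(model@bases[[v]]))
    for (i in seq_len(length(lv))) {
      if (!all(lv@present[[i]][sub]))
        stop("configuration ", pairKeys(lv)[i], " (", v,
             ") lacks required landmark(s) ",
             paste(sub[!lv@present[[i]][sub]], collapse = ", "))
      ps <- preshape(lv@coords[[i]][sub, , drop = FALSE])
      al <- opaAlign(model@mean_shapes[[v]], ps$points,
                     allow_reflection = FALSE)
      sc[i, ] <- (.flatten(al$aligned) - .flatten(model@mean_shapes[[v]])) %*%
        model@bases[[v]]
    }
    rownames(sc) <- pairKeys(lv)
    block_scores[[v]] <- sc
  }
  ids <- Reduce(intersect, lapply(block_scores, rownames))
  if (!length(ids)) stop("no test vertebrae present in all model views")
  scores <- do.call(cbind, lapply(block_scores,
                                  function(m) m[ids, , drop = FALSE]))
  z <- sweep(scores, 2, model@centre2) %*% model@rot2
  rownames(z) <- ids
  z
}

#' Classify test configurations with a trained model
#'
#' @param model a [VertebraClassifier-class].
#' @param x a [LandmarkSet-class] of test configurations.
#' @return data.frame with `id`, `label`, `posterior` (winning class), plus
#'   the full posterior matrix as attribute `"posteriors"`.
#' @export
predictClassifier <- function(model, x) {
  z <- standardizeAndScore(model, x)
  pr <- predictLDA(model@lda, z)
  out <- data.frame(id = rownames(z), label = pr$labels,
                    posterior = pr$posteriors[cbind(seq_len(nrow(z)),
                                match(pr$labels, model@lda@classes))],
                    stringsAsFactors = FALSE)
  attr(out, "posteriors") <- pr$posteriors
  out
}

#' Bootstrap accuracy of the two-stage classifier
#'
#' Repeats a stratified 70:30 train/test split: the classifier is trained
#' on the training part ([trainClassifier()]), the test part standardised
#' against the frozen training statistics and classified, and the
#' proportion of correct test classifications recorded. Fully reproducible
#' from `seed`.
#'
#' @param x a [LandmarkSet-class] (both views of every vertebra).
#' @param level classification level.
#' @param views views to use.
#' @param reps repetitions (default 100).
#' @param train_fraction training share (default 0.7); per-class training
#'   counts round up under stratification.
#' @param seed RNG seed.
#' @param stratified split per class (default `TRUE`); the non-stratified
#'   alternative splits the pooled vertebrae.
#' @param subsets,cum_var,priors passed to [trainClassifier()].
#' @return an [EvaluationReport-class].
#' @export
bootstrapAccuracy <- function(x, level, views = c("anterior", "sinistral"),
                              reps = 100, train_fraction = 0.7, seed = 1,
                              stratified = TRUE, subsets = NULL,
                              cum_var = 0.99, priors = "proportional") {
  stopifnot(is(x, "LandmarkSet"))
  per_view <- lapply(views, function(v) subsetConfigs(x, view = v))
  names(per_view) <- views
  ids <- Reduce(intersect, lapply(per_view, pairKeys))
  ref <- per_view[[1]][match(ids, pairKeys(per_view[[1]]))]
  labels <- .levelLabels(ref@info, level)
  counts <- table(labels)
  if (any(counts < 4))
    stop("class(es) too small to stratify a 70:30 split (need >= 4): ",
         paste(names(counts)[counts < 4], collapse = ", "))
  classes <- sort(names(counts))
  set.seed(seed)
  acc <- numeric(reps)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  for (r in seq_len(reps)) {
    if (stratified) {
      train_ids <- unlist(lapply(classes, function(cl) {
        cl_ids <- ids[labels == cl]
        sample(cl_ids, ceiling(train_fraction * length(cl_ids)))
      }))
    } else {
      train_ids <- sample(ids, ceiling(train_fraction * length(ids)))
    }
    test_ids <- setdiff(ids, train_ids)
    train_set <- x[pairKeys(x) %in% train_ids]
    test_set <- x[pairKeys(x) %in% test_ids]
    model <- suppressMessages(
      trainClassifier(train_set, level, views = views, subsets = subsets,
                      cum_var = cum_var, priors = priors))
    pred <- predictClassifier(model, test_set)
    truth <- labels[match(pred$id, ids)]
    acc[r] <- mean(pred$label == truth)
    tab <- unclass(table(factor(truth, levels = classes),
                         factor(pred$label, levels = classes)))
    conf <- conf + tab
  }
  new("EvaluationReport", accuracies = acc, mean = mean(acc),
      sd = sd(acc), confusion = conf, reps = as.integer(reps),
      train_fraction = train_fraction, seed = as.integer(seed),
      level = level, views = views)
}

#' Chained accuracy of a hierarchical identification
#'
#' The joint probability of a correct decision through successive
#' classification stages under stagewise independence: the product of the
#' per-stage accuracies. For example, classifying first to vertebra type
#' and then to family with stage accuracies 0.8953 and 0.9569 gives a
#' chained accuracy of 0.8567 (85.67%).
#'
#' @param stage_accuracies numeric vector of per-stage accuracies in
#'   `[0, 1]`.
#' @return the chained accuracy (scalar in `[0, 1]`).
#' @examples
#' hierarchicalAccuracy(c(0.8953, 0.9569))  # 0.8567...
#' @export
hierarchicalAccuracy <- function(stage_accuracies) {
  if (any(stage_accuracies < 0 | stage_accuracies > 1) ||
      any(!is.finite(stage_accuracies)))
    stop("stage accuracies must lie in [0, 1]")
  prod(stage_accuracies)
}
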
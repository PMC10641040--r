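## Fragment-aware identification of individual (possibly degraded) samples
## against the modern reference collection.
##
## Unlike the modern-material evaluation (where the test set is
## standardised against frozen training statistics), each archaeological
## sample joins the reference subset in a common GPA and first PCA: with a
## single sample among many references the consensus is still dominated by
## the reference material. The second PCA and the LDA are fitted on
## reference rows only, so the sample never influences the classifier.

#' Usable landmarks of a configuration
#'
#' The present landmarks of one configuration intersected with the
#' analysis subset for its view and vertebra type (arch tips always
#' excluded).
#'
#' @param x a [LandmarkSet-class].
#' @param i configuration index.
#' @param level analysis level (see [analysisSubset()]).
#' @return sorted integer vector of usable landmark indices.
#' @export
usableLandmarks <- function(x, i, level = "species") {
  stopifnot(is(x, "LandmarkSet"))
  sub <- analysisSubset(x@info$view[i], x@info$vertebra[i], level)
  sort(intersect(which(x@present[[i]]), sub))
}

## classify one sample at one chain level against a reference subset
.identifyLevel <- function(sample, reference, level, subset_for,
                           min_landmarks, cum_var, flags) {
  ref_ids <- unique(pairKeys(reference))
  ref1 <- reference[match(ref_ids, pairKeys(reference))]
  labels <- .levelLabels(ref1@info, level)
  ## drop reference classes too small for LDA
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    keep <- !(labels %in% small)
    ref_ids <- ref_ids[keep]; labels <- labels[keep]
    reference <- reference[pairKeys(reference) %in% ref_ids]
    flags <- c(flags, paste0("reference_class_dropped:",
                             paste(small, collapse = "/")))
  }
  if (length(unique(labels)) < 2)
    return(list(ok = FALSE, flags = c(flags, paste0(
      "chain_truncated_at_", level, ":fewer_than_2_reference_classes"))))
  sample_key <- unique(pairKeys(sample))
  block_scores <- list(); used <- list()
  for (view in .VIEWS) {
    srow <- which(sample@info$view == view)
    if (!length(srow)) next
    i <- srow[1]
    sub <- subset_for(view)
    usable <- sort(intersect(which(sample@present[[i]]), sub))
    if (length(usable) < min_landmarks) {
      flags <- c(flags, paste0("view_dropped:", view, "@", level))
      next
    }
    rv <- subsetConfigs(reference, view = view)
    ## references must be complete on the sample's usable landmarks
    ok <- vapply(seq_len(length(rv)),
                 function(j) all(rv@present[[j]][usable]), TRUE)
    rv <- rv[ok]
    if (length(rv) < 3) next
    joint <- c(rv, sample[i])
    al <- gpa(joint, subset = usable)
    sp <- fitShapePCA(al)
    block_scores[[view]] <- sp@scores
    used[[view]] <- usable
  }
  if (!length(block_scores))
    return(list(ok = FALSE, insufficient = TRUE, flags = flags))
  comb <- suppressMessages(combineViews(block_scores))
  ids <- rownames(comb@scores)
  if (!(sample_key %in% ids))
    return(list(ok = FALSE, insufficient = TRUE, flags = flags))
  ref_rows <- comb@scores[setdiff(ids, sample_key), , drop = FALSE]
  lab <- labels[match(rownames(ref_rows), ref_ids)]
  keep <- !is.na(lab)
  ref_rows <- ref_rows[keep, , drop = FALSE]; lab <- lab[keep]
  if (length(unique(lab)) < 2)
    return(list(ok = FALSE, flags = c(flags, paste0(
      "chain_truncated_at_", level, ":fewer_than_2_reference_classes"))))
  fit2 <- .fitSecondPCA(ref_rows, cum_var = cum_var,
                        cap = nrow(ref_rows) - length(unique(lab)))
  lda <- fitLDA(.applySecondPCA(fit2, ref_rows), lab)
  zs <- .applySecondPCA(fit2, comb@scores[sample_key, , drop = FALSE])
  pr <- predictLDA(lda, zs)
  if (length(block_scores) < 2)
    flags <- c(flags, paste0("single_view_only@", level))
  list(ok = TRUE, label = pr$labels[1],
       posterior = max(pr$posteriors[1, ]),
       views = names(block_scores), used = used, flags = flags)
}

#' Identify one (possibly fragmentary) vertebra against a reference
#'
#' Runs the hierarchical identification chain for a single sample.
#' `"full_chain"` first predicts the vertebra type from all non-atlas
#' references on the across-type landmark subset, then the family within
#' the predicted type, then the species within the predicted family.
#' `"given_type"` (the default, matching practice when the type is clear
#' from visual inspection) starts at family within the sample's recorded
#' type; atlas samples always use `given_type`. At every level, landmarks
#' absent from the sample are removed from every reference configuration,
#' the sample joins the per-view GPA and first PCA, and the second PCA and
#' LDA are fitted on reference rows only. A view with fewer than
#' `min_landmarks` usable landmarks is dropped; if no view is usable the
#' sample is unidentifiable and an error is raised.
#'
#' @param sample a [LandmarkSet-class] with the 1-2 views of one vertebra.
#' @param reference the modern reference [LandmarkSet-class], completed
#'   (missing landmarks estimated) beforehand.
#' @param mode `"given_type"` or `"full_chain"`.
#' @param min_landmarks minimum usable landmarks per view (default 3).
#' @param cum_var second-PCA retention rule (default 0.99).
#' @return an [IdentificationResult-class].
#' @export
identifySample <- function(sample, reference,
                           mode = c("given_type", "full_chain"),
                           min_landmarks = 3, cum_var = 0.99) {
  mode <- match.arg(mode)
  stopifnot(is(sample, "LandmarkSet"), is(reference, "LandmarkSet"))
  key <- unique(pairKeys(sample))
  if (length(key) != 1)
    stop("identifySample expects the views of exactly one vertebra")
  vt <- sample@info$vertebra[1]
  ## reserved query key so a sample can never collide with a reference row
  sample@info$sample_id <- ".query."
  flags <- character(0)
  if (vt == "atlas" && mode == "full_chain") {
    mode <- "given_type"
    flags <- c(flags, "atlas_forced_given_type")
  }
  levels <- if (mode == "full_chain")
    c("vertebra_type", "family", "species") else c("family", "species")
  cur_type <- vt; cur_family <- NULL
  decisions <- data.frame(level = character(0), label = character(0),
                          posterior = numeric(0), stringsAsFactors = FALSE)
  views_used <- character(0); landmarks_used <- list()
  for (level in levels) {
    if (level == "vertebra_type") {
      refs <- subsetConfigs(reference,
                            vertebra = c("cervical", "precaudal", "caudal"))
      subset_for <- function(view) landmarkScheme(view, "precaudal")$shared
    } else if (level == "family") {
      refs <- subsetConfigs(reference, vertebra = cur_type)
      subset_for <- local({
        ct <- cur_type
        function(view) analysisSubset(view, ct, "family")
      })
    } else {
      refs <- subsetConfigs(reference, vertebra = cur_type)
      refs <- refs[refs@info$family == cur_family]
      subset_for <- local({
        ct <- cur_type
        function(view) analysisSubset(view, ct, "species")
      })
    }
    if (!length(refs)) {
      flags <- c(flags, paste0("chain_truncated_at_", level,
                               ":no_references"))
      break
    }
    res <- .identifyLevel(sample, refs, level, subset_for, min_landmarks,
                          cum_var, flags)
    flags <- res$flags
    if (!res$ok) {
      if (isTRUE(res$insufficient) && nrow(decisions) == 0)
        stop("insufficient landmarks: sample ", key,
             " has fewer than ", min_landmarks,
             " usable landmarks in every view")
      if (isTRUE(res$insufficient))
        flags <- c(flags, paste0("chain_truncated_at_", level,
                                 ":insufficient_landmarks"))
      break
    }
    decisions <- rbind(decisions,
                       data.frame(level = level, label = res$label,
                                  posterior = res$posterior,
                                  stringsAsFactors = FALSE))
    views_used <- res$views
    landmarks_used <- res$used
    if (level == "vertebra_type") cur_type <- res$label
    if (level == "family") cur_family <- res$label
  }
  if (nrow(decisions) == 0)
    stop("sample ", key, " could not be identified at any level")
  new("IdentificationResult", sample_id = key, mode = mode,
      decisions = decisions, views_used = views_used,
      landmarks_used = landmarks_used, flags = unique(flags),
      chained_posterior = prod(decisions$posterior))
}

#' Identify a batch of samples
#'
#' Applies [identifySample()] to every vertebra in `samples`; per-sample
#' failures become flagged rows and the run continues. When the sample
#' metadata carry truth labels (synthetic material, or identifications
#' verified externally), a per-level percent-correct summary is attached
#' as attribute `"summary"`.
#'
#' @param samples a [LandmarkSet-class] of samples (1-2 views each).
#' @param reference completed modern reference [LandmarkSet-class].
#' @param mode,min_landmarks,cum_var passed to [identifySample()].
#' @return data.frame with one row per sample: `sample_id`, `mode`,
#'   per-level `label`/`posterior` columns, `views_used`, `flags`.
#' @export
identifyBatch <- function(samples, reference,
                          mode = c("given_type", "full_chain"),
                          min_landmarks = 3, cum_var = 0.99) {
  mode <- match.arg(mode)
  keys <- unique(pairKeys(samples))
  rows <- vector("list", length(keys))
  for (j in seq_along(keys)) {
    smp <- samples[pairKeys(samples) == keys[j]]
    row <- data.frame(sample_id = keys[j], mode = mode,
                      vertebra_type = NA_character_,
                      vertebra_type_posterior = NA_real_,
                      family = NA_character_, family_posterior = NA_real_,
                      species = NA_character_, species_posterior = NA_real_,
                      views_used = NA_character_, flags = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch(identifySample(smp, reference, mode = mode,
                                   min_landmarks = min_landmarks,
                                   cum_var = cum_var),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row$flags <- paste0("unidentifiable:", conditionMessage(res))
    } else {
      for (i in seq_len(nrow(res@decisions))) {
        lv <- res@decisions$level[i]
        row[[lv]] <- res@decisions$label[i]
        row[[paste0(lv, "_posterior")]] <- res@decisions$posterior[i]
      }
      row$views_used <- paste(res@views_used, collapse = "+")
      row$flags <- paste(res@flags, collapse = ";")
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  ## truth-based summary when metadata carry labels
  first <- samples[match(keys, pairKeys(samples))]
  truth <- data.frame(vertebra_type = first@info$vertebra,
                      family = first@info$family,
                      species = first@info$species,
                      stringsAsFactors = FALSE)
  summ <- vapply(c("vertebra_type", "family", "species"), function(lv) {
    got <- !is.na(out[[lv]])
    if (!any(got)) return(NA_real_)
    100 * mean(out[[lv]][got] == truth[[lv]][got])
  }, 0)
  attr(out, "summary") <- summ
  out
}
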
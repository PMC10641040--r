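## Workflow orchestration: ingest -> complete -> screen -> evaluate /
## identify, with a manifest for reproducibility. Configurations are plain
## lists, optionally loaded from YAML.

#' Load a run configuration
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

.ingest <- function(input) {
  if (!is.null(input$tps)) {
    paths <- input$tps
    if (length(paths) == 1 && dir.exists(paths))
      paths <- list.files(paths, pattern = "\\.[Tt][Pp][Ss]$",
                          full.names = TRUE)
    if (!length(paths)) stop("no TPS files found")
    sets <- lapply(sort(paths), readTPS)
    do.call(c, sets)
  } else if (!is.null(input$synthetic)) {
    spec <- do.call(syntheticSpec, input$synthetic)
    simulateDataset(spec)
  } else stop("input must specify either $tps or $synthetic")
}

## estimate missing landmarks per (view, vertebra class) group
.completeDataset <- function(x, min_present = 4) {
  out <- NULL
  for (view in unique(x@info$view)) {
    for (cls in unique(.typeClass(x@info$vertebra))) {
      idx <- x@info$view == view & .typeClass(x@info$vertebra) == cls
      if (!any(idx)) next
      grp <- x[idx]
      grp <- tryCatch(estimateMissing(grp, min_present = min_present),
                      error = function(e) {
                        warning("group ", view, "/", cls, ": ",
                                conditionMessage(e))
                        grp
                      })
      out <- if (is.null(out)) grp else c(out, grp)
    }
  }
  out
}

## flag outlier vertebrae per (view, type) on the type-specific subset and
## drop them dataset-wide; returns list(data, removed)
.screenOutliers <- function(x, k = 1.5) {
  removed <- character(0)
  for (view in unique(x@info$view)) {
    for (ty in unique(x@info$vertebra)) {
      idx <- which(x@info$view == view & x@info$vertebra == ty)
      if (length(idx) < 4) next
      grp <- x[idx]
      sub <- analysisSubset(view, ty, "family")
      ok <- vapply(seq_len(length(grp)),
                   function(i) all(grp@present[[i]][sub]), TRUE)
      if (sum(ok) < 4) next
      al <- gpa(grp[ok], subset = sub)
      fl <- flagOutliers(al, k = k)
      removed <- c(removed, al@ids[fl])
    }
  }
  removed <- unique(removed)
  list(data = x[!(pairKeys(x) %in% removed)], removed = removed)
}

.writeManifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "flatmorph",
    version = as.character(utils::packageVersion("flatmorph")),
    seed = seed, config = config), extra)
  yaml::write_yaml(manifest, path)
}

#' Run the modern-material classification evaluation
#'
#' Executes the evaluation workflow: ingest (TPS files or the synthetic
#' generator), missing-landmark estimation, IQR outlier screening, then
#' bootstrap classification accuracy for each requested level and view
#' (anterior, sinistral, combined), with family/species levels evaluated
#' per vertebra type. Writes an accuracy summary, per-repetition
#' accuracies, and a reproducibility manifest to the output directory.
#'
#' @param config list (or YAML via [readRunConfig()]) with elements
#'   `input` (either `tps` paths or `synthetic` spec parameters),
#'   `output_dir`, and optionally `levels`, `views`, `reps`,
#'   `train_fraction`, `seed`, `outlier_k`.
#' @return data.frame of accuracy summaries (also written to
#'   `accuracy_summary.csv`), invisibly.
#' @export
runEvaluate <- function(config) {
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  reps <- config$reps %||% 100L
  frac <- config$train_fraction %||% 0.7
  levels <- config$levels %||% c("vertebra_type", "family", "species")
  view_sets <- config$views %||% list(anterior = "anterior",
                                      sinistral = "sinistral",
                                      combined = c("anterior", "sinistral"))
  x <- .ingest(config$input)
  x <- .completeDataset(x)
  scr <- .screenOutliers(x, k = config$outlier_k %||% 1.5)
  x <- scr$data
  rows <- list(); all_acc <- list()
  jobs <- list()
  for (level in levels) {
    if (level == "vertebra_type") {
      jobs[[length(jobs) + 1]] <- list(level = level, subset_name = "all",
        vertebra = c("cervical", "precaudal", "caudal"))
    } else {
      for (ty in intersect(.VERTEBRA_TYPES, unique(x@info$vertebra)))
        jobs[[length(jobs) + 1]] <- list(level = level, subset_name = ty,
                                         vertebra = ty)
    }
  }
  for (job in jobs) {
    dat <- subsetConfigs(x, vertebra = job$vertebra)
    if (!length(dat)) next
    row <- data.frame(level = job$level, subset = job$subset_name,
                      stringsAsFactors = FALSE)
    for (vs in names(view_sets)) {
      rep_name <- paste(job$level, job$subset_name, vs, sep = "_")
      rep_res <- tryCatch(
        bootstrapAccuracy(dat, job$level, views = view_sets[[vs]],
                          reps = reps, train_fraction = frac, seed = seed),
        error = function(e) e)
      if (inherits(rep_res, "error")) {
        row[[paste0(vs, "_mean")]] <- NA_real_
        row[[paste0(vs, "_sd")]] <- NA_real_
        row[[paste0(vs, "_note")]] <- conditionMessage(rep_res)
      } else {
        row[[paste0(vs, "_mean")]] <- rep_res@mean
        row[[paste0(vs, "_sd")]] <- rep_res@sd
        row[[paste0(vs, "_note")]] <- ""
        all_acc[[rep_name]] <- rep_res@accuracies
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  summary_df <- do.call(rbind, rows)
  write.csv(summary_df, file.path(out_dir, "accuracy_summary.csv"),
            row.names = FALSE)
  if (length(all_acc)) {
    acc_df <- data.frame(analysis = rep(names(all_acc),
                                        lengths(all_acc)),
                         rep = unlist(lapply(all_acc, seq_along)),
                         accuracy = unlist(all_acc), row.names = NULL)
    write.csv(acc_df, file.path(out_dir, "accuracies.csv"),
              row.names = FALSE)
  }
  .writeManifest(file.path(out_dir, "manifest.yaml"), config, seed,
                 list(outliers_removed = scr$removed,
                      n_configurations = length(x)))
  invisible(summary_df)
}

#' Run batch identification of archaeological-style samples
#'
#' Ingests a reference dataset and a sample dataset, completes the
#' reference (missing-landmark estimation), identifies every sample with
#' [identifyBatch()], and writes the per-sample results table, a per-level
#' percent-correct summary (when truth labels are available) and a
#' manifest.
#'
#' @param config list with `reference` and `samples` input blocks (same
#'   format as `runEvaluate`'s `input`), `output_dir`, and optionally
#'   `mode`, `min_landmarks`, `seed`.
#' @return the results data.frame, invisibly.
#' @export
runIdentify <- function(config) {
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  reference <- .completeDataset(.ingest(config$reference))
  samples <- .ingest(config$samples)
  if (!is.null(config$degrade))
    samples <- do.call(degradeDataset, c(list(samples), config$degrade))
  res <- identifyBatch(samples, reference,
                       mode = config$mode %||% "given_type",
                       min_landmarks = config$min_landmarks %||% 3)
  write.csv(res, file.path(out_dir, "identifications.csv"),
            row.names = FALSE)
  summ <- attr(res, "summary")
  write.csv(data.frame(level = names(summ), percent_correct = summ,
                       row.names = NULL),
            file.path(out_dir, "identification_summary.csv"),
            row.names = FALSE)
  .writeManifest(file.path(out_dir, "manifest.yaml"), config, seed,
                 list(n_samples = length(unique(pairKeys(samples)))))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
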
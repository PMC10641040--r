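## Synthetic two-view landmark data with the statistical structure the
## pipeline assumes: per-taxon mean shapes nested in families, vertebra-type
## offsets, isotropic within-taxon variation, digitisation nuisance
## (rotation/translation/scale), mirror forms, and taphonomic degradation.

#' Construct a synthetic-data specification
#'
#' Defaults mirror the scale of a modern flatfish reference collection:
#' 19 taxa in 5 families with per-taxon specimen counts
#' (3,2,5,7,5,6,7,10,6,1,3,4,3,1,1,1,1,2,5), 10 vertebrae per specimen
#' (1 atlas + 3 cervical + 3 precaudal + 3 caudal), and mirror forms in
#' 40% of the largest taxon's specimens. Shape parameters are in units of
#' a unit-centroid-size template: `within_sd` is the isotropic per-landmark
#' coordinate SD, `separation` and `type_effect` are between-group
#' mean-shape distances expressed in multiples of `within_sd`.
#'
#' @param taxa_per_family named integer vector: taxa per family.
#' @param specimens_per_taxon specimens per taxon (recycled across taxa).
#' @param types vertebra types to generate.
#' @param n_atlas,n_per_type vertebrae per specimen: atlas count and count
#'   per non-atlas type.
#' @param separation between-taxon mean-shape distance, in `within_sd`
#'   units (default 4).
#' @param within_sd within-taxon isotropic landmark SD (default 0.02).
#' @param type_effect between-type mean-shape distance, in `within_sd`
#'   units (default 6).
#' @param mirror_fraction fraction of the mirror taxon's specimens
#'   generated as mirror (left-eyed) forms (default 0.4).
#' @param mirror_taxon taxon index carrying mirror forms (default: the
#'   taxon with most specimens).
#' @param rotation_range,translation_range,scale_range,digitisation_range
#'   uniform nuisance ranges: rotation (radians), translation (cm),
#'   physical size factor, digitiser units per cm (stored in TPS with
#'   `SCALE = 1/factor`).
#' @param structural_missing mark the structurally absent cervical
#'   landmarks as missing (default `TRUE`, as digitised in practice).
#' @param seed RNG seed (Mersenne-Twister); all generator output is a
#'   deterministic function of the spec.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(taxa_per_family = c(FAA = 1L, FAB = 1L,
                                              FAC = 7L, FAD = 6L,
                                              FAE = 4L),
                          specimens_per_taxon = c(3L, 2L, 5L, 7L, 5L, 6L,
                                                  7L, 10L, 6L, 1L, 3L, 4L,
                                                  3L, 1L, 1L, 1L, 1L, 2L,
                                                  5L),
                          types = c("atlas", "cervical", "precaudal",
                                    "caudal"),
                          n_atlas = 1L, n_per_type = 3L,
                          separation = 4, within_sd = 0.02,
                          type_effect = 6, mirror_fraction = 0.4,
                          mirror_taxon = NULL,
                          rotation_range = c(-pi, pi),
                          translation_range = c(-5, 5),
                          scale_range = c(0.75, 1.25),
                          digitisation_range = c(50, 200),
                          structural_missing = TRUE, seed = 1L) {
  taxa_per_family <- unlist(taxa_per_family)   # accept YAML-style maps
  specimens_per_taxon <- unlist(specimens_per_taxon)
  n_taxa <- sum(taxa_per_family)
  specimens_per_taxon <- as.integer(rep(specimens_per_taxon,
                                        length.out = n_taxa))
  if (is.null(mirror_taxon))
    mirror_taxon <- which.max(specimens_per_taxon)
  if (is.null(names(taxa_per_family)))
    names(taxa_per_family) <- sprintf("FA%s",
                                      LETTERS[seq_along(taxa_per_family)])
  tpf <- as.integer(taxa_per_family)
  names(tpf) <- names(taxa_per_family)
  new("SyntheticSpec",
      taxa_per_family = tpf,
      specimens_per_taxon = specimens_per_taxon,
      types = types, n_atlas = as.integer(n_atlas),
      n_per_type = as.integer(n_per_type), separation = separation,
      within_sd = within_sd, type_effect = type_effect,
      mirror_fraction = mirror_fraction,
      mirror_taxon = as.integer(mirror_taxon),
      rotation_range = rotation_range,
      translation_range = translation_range, scale_range = scale_range,
      digitisation_range = digitisation_range,
      structural_missing = structural_missing, seed = as.integer(seed))
}

## taxon/family bookkeeping derived from a spec
.taxonTable <- function(spec) {
  fams <- names(spec@taxa_per_family)
  family <- rep(fams, spec@taxa_per_family)
  taxon <- sprintf("T%02d", seq_along(family))
  data.frame(taxon = taxon, family = family,
             specimens = spec@specimens_per_taxon,
             stringsAsFactors = FALSE)
}

## Deterministic base template: irregular ring plus appendage points (the
## appendages occupy the leading indices, where the schemes put arch and
## spina tips). Asymmetric by construction so mirror forms are detectable.
.baseTemplate <- function(k, view) {
  n_app <- max(1L, as.integer(round(k / 4)))
  n_ring <- k - n_app
  th_app <- pi / 2 + 2.399963 * (seq_len(n_app) - 1)   # golden-angle fan
  app <- cbind((2 + 0.12 * seq_len(n_app)) * cos(th_app),
               (2 + 0.12 * seq_len(n_app)) * sin(th_app))
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring + 0.3
  r <- 1 + 0.15 * sin(3 * th + 0.7) + 0.07 * cos(2 * th)
  ring <- cbind(r * cos(th), r * sin(th))
  pts <- rbind(app, ring)
  if (view == "sinistral") pts[, 1] <- 1.2 * pts[, 1]
  ## mild fixed irregularity to break any residual symmetry
  i <- seq_len(k)
  pts[, 1] <- pts[, 1] + 0.05 * cos(7 * i)
  pts[, 2] <- pts[, 2] + 0.04 * sin(5 * i + 1)
  preshape(pts)$points
}

## templates drawn from the CURRENT RNG stream (callers seed it)
.drawTemplates <- function(spec) {
  tt <- .taxonTable(spec)
  n_taxa <- nrow(tt)
  fams <- names(spec@taxa_per_family)
  classes <- unique(.typeClass(spec@types))
  other_types <- setdiff(spec@types, "atlas")
  out <- list()
  for (view in .VIEWS) {
    out[[view]] <- list()
    for (cls in classes) {
      k <- .SCHEMES[[paste(view, cls, sep = "_")]]$size
      base <- .baseTemplate(k, view)
      tau <- spec@separation * spec@within_sd / sqrt(4 * k)
      ## family and taxon effects split the between-taxon variance equally
      fam_off <- matrix(rnorm(length(fams) * 2 * k, 0, tau / sqrt(2)),
                        length(fams), 2 * k, dimnames = list(fams, NULL))
      tax_off <- matrix(rnorm(n_taxa * 2 * k, 0, tau / sqrt(2)),
                        n_taxa, 2 * k, dimnames = list(tt$taxon, NULL))
      tau_ty <- spec@type_effect * spec@within_sd / sqrt(4 * k)
      cls_types <- if (cls == "atlas") "atlas" else other_types
      type_off <- matrix(rnorm(length(cls_types) * 2 * k, 0, tau_ty),
                         length(cls_types), 2 * k,
                         dimnames = list(cls_types, NULL))
      for (ty in cls_types) {
        out[[view]][[ty]] <- lapply(seq_len(n_taxa), function(ti) {
          base + .unflatten(type_off[ty, ] + fam_off[tt$family[ti], ] +
                            tax_off[ti, ])
        })
        names(out[[view]][[ty]]) <- tt$taxon
      }
    }
  }
  out
}

#' Per-taxon, per-type, per-view template mean shapes
#'
#' Draws the template hierarchy once from the spec's seed: a deterministic
#' base polygon per view/vertebra class, Gaussian vertebra-type offsets
#' scaled to `type_effect`, and Gaussian taxon offsets (nested in family
#' offsets) scaled so the mean pairwise between-taxon template distance is
#' about `separation * within_sd`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return nested list `templates[[view]][[type]][[taxon]]` of k x 2
#'   matrices (unit-size shape units).
#' @export
makeTemplates <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  ks <- vapply(unique(.typeClass(spec@types)), function(cls)
    .SCHEMES[[paste("anterior", cls, sep = "_")]]$size, 0L)
  if (any(ks < 3)) stop("landmark count below 3")
  set.seed(spec@seed)
  .drawTemplates(spec)
}

#' Simulate a two-view modern-style landmark dataset
#'
#' For every vertebra of every specimen, draws its shape as the
#' taxon/type/view template plus isotropic Gaussian landmark noise
#' (`within_sd`), applies independent digitisation nuisance per view
#' (rotation, translation, physical size factor), mirrors (x-negation
#' before the nuisance) the designated fraction of the mirror taxon's
#' specimens, and emits paired anterior/sinistral configurations with full
#' metadata. Output is a deterministic function of the spec (including its
#' seed) and round-trips through [writeTPS()]/[readTPS()].
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [LandmarkSet-class] (coordinates in cm).
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed)
  templates <- .drawTemplates(spec)
  tt <- .taxonTable(spec)
  other_types <- setdiff(spec@types, "atlas")
  schedule <- c(rep("atlas", if ("atlas" %in% spec@types) spec@n_atlas
                else 0L),
                rep(other_types, each = spec@n_per_type))
  coords <- list(); present <- list(); rows <- list()
  rec <- 0L; spec_no <- 0L
  for (ti in seq_len(nrow(tt))) {
    n_spec <- tt$specimens[ti]
    n_mirror <- if (ti == spec@mirror_taxon)
      round(spec@mirror_fraction * n_spec) else 0L
    for (si in seq_len(n_spec)) {
      spec_no <- spec_no + 1L
      spec_id <- sprintf("SP%03d", spec_no)
      mirrored <- si <= n_mirror
      for (vi in seq_along(schedule)) {
        ty <- schedule[vi]
        sample_id <- sprintf("%sV%02d", spec_id, vi)
        for (view in .VIEWS) {
          tmpl <- templates[[view]][[ty]][[ti]]
          k <- nrow(tmpl)
          shape <- tmpl + matrix(rnorm(2 * k, 0, spec@within_sd), k, 2)
          if (mirrored) shape[, 1] <- -shape[, 1]
          theta <- runif(1, spec@rotation_range[1], spec@rotation_range[2])
          size <- runif(1, spec@scale_range[1], spec@scale_range[2])
          shift <- runif(2, spec@translation_range[1],
                         spec@translation_range[2])
          xy <- size * .rotate(shape, theta)
          xy[, 1] <- xy[, 1] + shift[1]
          xy[, 2] <- xy[, 2] + shift[2]
          digit <- runif(1, spec@digitisation_range[1],
                         spec@digitisation_range[2])
          pres <- rep(TRUE, k)
          if (ty == "cervical" && spec@structural_missing) {
            absent <- landmarkScheme(view, "cervical")$cervical_absent
            pres[absent] <- FALSE
            xy[absent, ] <- NA_real_
          }
          rec <- rec + 1L
          coords[[rec]] <- xy
          present[[rec]] <- pres
          rows[[rec]] <- data.frame(
            order = rec, sample_id = sample_id, vertebra = ty, view = view,
            family = tt$family[ti], genus = tt$taxon[ti],
            species = tt$taxon[ti], provenance = "modern",
            form = if (mirrored) "mirror" else "normal",
            scale = 1 / digit, scaled = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  LandmarkSet(coords, do.call(rbind, rows), present = present)
}

#' Degrade a dataset into archaeological-style material
#'
#' Drops landmarks independently, either uniformly at rate `p_loss` or with
#' doubled loss probability on the arch/spina-tip landmarks
#' (`"tip_biased"`, emulating fragmentation concentrating on arches and
#' spines), optionally adds small Gaussian coordinate deformation, and
#' switches provenance to archaeological.
#'
#' @param x a [LandmarkSet-class].
#' @param loss_model `"tip_biased"` (default) or `"uniform"`.
#' @param p_loss baseline per-landmark loss probability in `[0, 1]`; tip
#'   landmarks lose at `min(1, 2 * p_loss)` under `"tip_biased"`.
#' @param deform_sd SD of added Gaussian coordinate noise in cm
#'   (default 0).
#' @param seed RNG seed.
#' @return the degraded [LandmarkSet-class].
#' @export
degradeDataset <- function(x, loss_model = c("tip_biased", "uniform"),
                           p_loss, deform_sd = 0, seed = 1L) {
  stopifnot(is(x, "LandmarkSet"), p_loss >= 0, p_loss <= 1)
  loss_model <- match.arg(loss_model)
  set.seed(seed)
  for (i in seq_along(x@coords)) {
    k <- nrow(x@coords[[i]])
    p <- rep(p_loss, k)
    if (loss_model == "tip_biased") {
      sch <- .schemeForSize(x@info$view[i], k)
      tips <- if (!is.null(sch)) sch$tips
              else seq_len(max(1L, as.integer(round(k / 4))))
      p[tips] <- pmin(1, 2 * p_loss)
    }
    drop <- runif(k) < p
    if (deform_sd > 0) {
      pres <- x@present[[i]]
      x@coords[[i]][pres, ] <- x@coords[[i]][pres, , drop = FALSE] +
        matrix(rnorm(2 * sum(pres), 0, deform_sd), sum(pres), 2)
    }
    gone <- drop & x@present[[i]]
    x@coords[[i]][gone, ] <- NA_real_
    x@present[[i]][gone] <- FALSE
    x@estimated[[i]][gone] <- FALSE
  }
  x@info$provenance <- "archaeological"
  x
}
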
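## Landmark schemes for the two photographic views and the two structural
## vertebra classes (the atlas carries its own configuration; cervical,
## precaudal and caudal vertebrae share one configuration per view).

.VERTEBRA_TYPES <- c("atlas", "cervical", "precaudal", "caudal")
.VIEWS <- c("anterior", "sinistral")
.PROVENANCES <- c("modern", "archaeological")

.typeClass <- function(vertebra_type) {
  ifelse(vertebra_type == "atlas", "atlas", "other")
}

## size: landmarks digitised per configuration
## arch_tips: tips of neural/haemal arches, excluded from every analysis
##   because they rarely survive in archaeological bone
## cervical_absent: landmarks on structures that cervical vertebrae lack
## shared: landmarks homologous across cervical/precaudal/caudal, used for
##   the across-type (vertebra-type level) analyses
## tips: arch tips plus spina tips, the loci where taphonomic fragmentation
##   concentrates (used by the tip-biased degradation model)
.SCHEMES <- list(
  anterior_atlas = list(
    view = "anterior", vertebra_class = "atlas", size = 13L,
    arch_tips = 1L, cervical_absent = integer(0),
    shared = integer(0), tips = 1L),
  anterior_other = list(
    view = "anterior", vertebra_class = "other", size = 19L,
    arch_tips = 1:3, cervical_absent = c(2L, 3L, 9L, 10L, 11L, 12L),
    shared = c(4:8, 13:19), tips = c(1:3, 18L, 19L)),
  sinistral_atlas = list(
    view = "sinistral", vertebra_class = "atlas", size = 9L,
    arch_tips = 1L, cervical_absent = integer(0),
    shared = integer(0), tips = 1L),
  sinistral_other = list(
    view = "sinistral", vertebra_class = "other", size = 12L,
    arch_tips = 1:2, cervical_absent = c(11L, 12L),
    shared = 3:10, tips = c(1L, 2L, 4L, 7L)))

#' Landmark scheme for a view and vertebra type
#'
#' Returns the landmark configuration metadata for one photographic view of
#' one vertebra type: the number of landmarks, the arch-tip landmarks that
#' are excluded from all analyses, the landmarks structurally absent in
#' cervical vertebrae, and the landmark subset shared across the non-atlas
#' vertebra types.
#'
#' @param view `"anterior"` or `"sinistral"`.
#' @param vertebra_type one of `"atlas"`, `"cervical"`, `"precaudal"`,
#'   `"caudal"` (the latter three share a scheme).
#' @return a list with elements `view`, `vertebra_class`, `size`,
#'   `arch_tips`, `cervical_absent`, `shared` and `tips` (1-based indices).
#' @examples
#' landmarkScheme("anterior", "precaudal")$size  # 19
#' @export
landmarkScheme <- function(view, vertebra_type) {
  view <- match.arg(view, .VIEWS)
  vertebra_type <- match.arg(vertebra_type, .VERTEBRA_TYPES)
  .SCHEMES[[paste(view, .typeClass(vertebra_type), sep = "_")]]
}

## Landmarks actually analysed for a (view, vertebra type) at a given level.
## Arch tips are always dropped; the across-type level keeps only landmarks
## homologous across cervical/precaudal/caudal; cervical configurations
## additionally drop the structurally absent landmarks.
#' Analysis landmark subset
#'
#' The landmark indices entering an analysis for a given view, vertebra type
#' and taxonomic level. Arch-tip landmarks are always excluded; analyses at
#' the vertebra-type level use only landmarks shared across the non-atlas
#' types; cervical vertebrae additionally exclude landmarks on structures
#' they lack.
#'
#' @param view `"anterior"` or `"sinistral"`.
#' @param vertebra_type vertebra type of the configurations analysed.
#' @param level `"vertebra_type"` for the across-type analysis, anything
#'   else (e.g. `"family"`, `"species"`) for the type-specific analysis.
#' @return sorted integer vector of 1-based landmark indices.
#' @export
analysisSubset <- function(view, vertebra_type, level = "family") {
  sch <- landmarkScheme(view, vertebra_type)
  if (identical(level, "vertebra_type")) {
    if (vertebra_type == "atlas")
      stop("the across-type analysis excludes atlas vertebrae")
    return(sch$shared)
  }
  keep <- setdiff(seq_len(sch$size), sch$arch_tips)
  if (vertebra_type == "cervical")
    keep <- setdiff(keep, sch$cervical_absent)
  sort(keep)
}

.schemeForSize <- function(view, n) {
  for (sch in .SCHEMES)
    if (sch$view == view && sch$size == n) return(sch)
  NULL
}
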
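## TPS landmark file I/O (tpsDig dialect) and record-identifier parsing.
##
## A record is:
##   LM=<n>
##   <n> lines of "x y" in file (image) units
##   IMAGE=<...>      (optional)
##   ID=<identifier>  (mandatory)
##   SCALE=<s>        (optional; cm per file unit)
## Missing landmarks are encoded as a sentinel coordinate pair.

.TYPE_TOKENS <- c(atlas = "AT", cervical = "CE", precaudal = "PC",
                  caudal = "CA")
.VIEW_TOKENS <- c(anterior = "A", sinistral = "S")

#' Parse a TPS record identifier into specimen metadata
#'
#' Identifiers follow the convention
#' `ORDER_SAMPLE_TYPE_VIEW_FAMILY_GENUS_SPECIES` with underscores as
#' delimiters: a zero-padded order number, the sample identifier, a
#' vertebra-type token (`AT`, `CE`, `PC`, `CA`), a view token (`A`, `S`) and
#' three taxon codes.
#'
#' @param id_string identifier string, e.g.
#'   `"0042_RBINS2765_PC_A_PLE_PLA_PLA"`.
#' @return a list with fields `order`, `sample_id`, `vertebra`, `view`,
#'   `family`, `genus`, `species` (codes upper-cased).
#' @examples
#' parseIdentifier("0001_YZL10_AT_S_SOL_SOL_SOL")$vertebra  # "atlas"
#' @export
parseIdentifier <- function(id_string) {
  tok <- strsplit(id_string, "_", fixed = TRUE)[[1]]
  if (length(tok) != 7)
    stop("identifier '", id_string, "' has ", length(tok),
         " tokens; expected 7 (ORDER_SAMPLE_TYPE_VIEW_FAM_GEN_SP)")
  ord <- suppressWarnings(as.integer(tok[1]))
  if (is.na(ord) || ord < 1)
    stop("identifier '", id_string, "': order token '", tok[1],
         "' is not a positive integer")
  vert <- names(.TYPE_TOKENS)[match(toupper(tok[3]), .TYPE_TOKENS)]
  if (is.na(vert))
    stop("identifier '", id_string, "': unrecognised vertebra-type token '",
         tok[3], "'")
  view <- names(.VIEW_TOKENS)[match(toupper(tok[4]), .VIEW_TOKENS)]
  if (is.na(view))
    stop("identifier '", id_string, "': unrecognised view token '",
         tok[4], "'")
  list(order = ord, sample_id = tok[2], vertebra = vert, view = view,
       family = toupper(tok[5]), genus = toupper(tok[6]),
       species = toupper(tok[7]))
}

#' Build a record identifier from metadata
#'
#' Inverse of [parseIdentifier()].
#'
#' @param info a list or one-row data.frame with fields `order`,
#'   `sample_id`, `vertebra`, `view`, `family`, `genus`, `species`.
#' @return identifier string.
#' @export
makeIdentifier <- function(info) {
  sprintf("%04d_%s_%s_%s_%s_%s_%s", as.integer(info$order), info$sample_id,
          .TYPE_TOKENS[[info$vertebra]], .VIEW_TOKENS[[info$view]],
          toupper(info$family), toupper(info$genus), toupper(info$species))
}

.isMissingPair <- function(xy, policy) {
  if (policy == "sentinel_pair") xy[1] == -1 & xy[2] == -1
  else xy[1] < 0 & xy[2] < 0
}

#' Read a TPS landmark file
#'
#' Reads tpsDig-style records into a [LandmarkSet-class]. Coordinates are
#' multiplied by each record's SCALE factor so the returned units are cm;
#' records without a SCALE line are kept in file units and flagged
#' (`scaled = FALSE`) with a warning. Landmarks matching the missing
#' encoding get `present = FALSE` and `NA` coordinates.
#'
#' @param path TPS file path.
#' @param missing_policy `"sentinel_pair"` (both coordinates exactly -1,
#'   the default) or `"negative_any"` (any pair with both coordinates
#'   negative).
#' @param check_scheme error when a record's landmark count does not match
#'   the scheme for its declared view and vertebra type (default `TRUE`).
#' @return a [LandmarkSet-class] with one configuration per record, in file
#'   order.
#' @seealso [writeTPS()], [parseIdentifier()]
#' @export
readTPS <- function(path, missing_policy = c("sentinel_pair",
                                             "negative_any"),
                    check_scheme = TRUE) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^LM=", lines)
  coords <- list(); present <- list(); info <- NULL
  rec_end <- c(starts[-1] - 1L, length(lines))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:rec_end[r]]
    block <- block[nzchar(block)]
    n <- suppressWarnings(as.integer(sub("^LM=", "", block[1])))
    if (is.na(n) || n < 0)
      stop("record ", r, ": malformed LM= line '", block[1], "'")
    body <- block[-1]
    kw <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!kw]
    if (length(coord_lines) != n)
      stop("record ", r, ": LM=", n, " but ", length(coord_lines),
           " coordinate lines")
    id_line <- grep("^ID=", body, value = TRUE)
    if (length(id_line) != 1)
      stop("record ", r, ": expected exactly one ID= line")
    id <- sub("^ID=", "", id_line)
    meta <- parseIdentifier(id)
    xy <- matrix(NA_real_, n, 2)
    pres <- rep(TRUE, n)
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[i],
                                                "[[:space:]]+")[[1]]))
      if (length(v) != 2 || any(is.na(v)))
        stop("record ", r, " (", id, "): malformed coordinate line '",
             coord_lines[i], "'")
      if (.isMissingPair(v, missing_policy)) pres[i] <- FALSE
      else xy[i, ] <- v
    }
    scale_line <- grep("^SCALE=", body, value = TRUE)
    if (length(scale_line)) {
      sc <- as.numeric(sub("^SCALE=", "", scale_line[1]))
      xy <- xy * sc
      scaled <- TRUE
    } else {
      sc <- 1
      scaled <- FALSE
      warning("record ", r, " (", id, "): no SCALE line; ",
              "coordinates left in file units")
    }
    if (check_scheme) {
      sch <- landmarkScheme(meta$view, meta$vertebra)
      if (sch$size != n)
        stop("record ", r, " (", id, "): ", n, " landmarks but the ",
             meta$view, "/", .typeClass(meta$vertebra), " scheme has ",
             sch$size)
    }
    coords[[r]] <- xy
    present[[r]] <- pres
    row <- data.frame(order = meta$order, sample_id = meta$sample_id,
                      vertebra = meta$vertebra, view = meta$view,
                      family = meta$family, genus = meta$genus,
                      species = meta$species, provenance = "modern",
                      form = "normal", scale = sc, scaled = scaled,
                      stringsAsFactors = FALSE)
    info <- if (is.null(info)) row else rbind(info, row)
  }
  if (is.null(info))
    return(LandmarkSet(list(), data.frame(order = integer(0),
                                          sample_id = character(0),
                                          vertebra = character(0),
                                          view = character(0))[0, ]))
  LandmarkSet(coords, info, present = present)
}

#' Write a TPS landmark file
#'
#' Writes a [LandmarkSet-class] as tpsDig-style records in input order.
#' Coordinates are stored in file units (`cm / scale`) with a SCALE line
#' restoring cm on read; absent landmarks are written as the sentinel pair
#' `-1 -1`.
#'
#' @param x a [LandmarkSet-class].
#' @param path output file path.
#' @param digits decimal places for stored coordinates (default 5, the
#'   tpsDig convention).
#' @return `path`, invisibly.
#' @export
writeTPS <- function(x, path, digits = 5) {
  stopifnot(is(x, "LandmarkSet"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f %.", digits, "f")
  for (i in seq_along(x@coords)) {
    xy <- x@coords[[i]]
    pres <- x@present[[i]]
    inf <- x@info[i, ]
    sc <- if (inf$scaled) inf$scale else 1
    out <- c(sprintf("LM=%d", nrow(xy)))
    for (j in seq_len(nrow(xy))) {
      out <- c(out, if (pres[j]) sprintf(fmt, xy[j, 1] / sc, xy[j, 2] / sc)
               else sprintf(fmt, -1, -1))
    }
    out <- c(out, paste0("ID=", makeIdentifier(inf)))
    if (inf$scaled) out <- c(out, sprintf("SCALE=%.10g", sc))
    writeLines(out, con)
  }
  invisible(path)
}

#' Metadata table for a LandmarkSet
#'
#' One row per configuration: identifier fields plus the number of present
#' landmarks; suitable for delimited export.
#'
#' @param x a [LandmarkSet-class].
#' @return data.frame.
#' @export
metadataTable <- function(x) {
  stopifnot(is(x, "LandmarkSet"))
  df <- x@info
  df$id <- vapply(seq_len(nrow(df)), function(i) makeIdentifier(df[i, ]), "")
  df$n_present <- vapply(x@present, sum, 0L)
  df$n_landmarks <- vapply(x@coords, nrow, 0L)
  df
}
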
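#' Define named helix/loop segments
#'
#' A segment definition carries inclusive author-numbered residue ranges for
#' each named segment (TMs and loops), optional pivot residues that split a
#' helix into two compartments at a proline kink, and optional
#' Ballesteros-Weinstein (BW) anchors giving, for each helix index, the
#' residue that carries the generic position x.50.
#'
#' @param segments named list of \code{c(first, last)} integer pairs
#' @param pivots named list/vector: segment name -> pivot residue number
#' @param bw_anchors named list/vector: helix index ("1".."8") -> residue
#'   number carrying x.50.  An anchor may alternatively be given as
#'   \code{c(residue, position)} when the reference residue carries a generic
#'   position other than 50 (e.g. 3.39 = 203).
#' @return object of class \code{segment_definition}
#' @export
segment_definition <- function(segments, pivots = list(), bw_anchors = list()) {
  stopifnot(is.list(segments), length(segments) > 0)
  ranges <- lapply(segments, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2])
      stop("each segment must be c(first, last) with first <= last")
    r
  })
  # ranges must not overlap
  ord <- order(vapply(ranges, `[`, integer(1), 1))
  sorted <- ranges[ord]
  for (i in seq_along(sorted)[-1])
    if (sorted[[i]][1] <= sorted[[i - 1]][2])
      stop("segment ranges overlap: ", names(sorted)[i - 1], " and ", names(sorted)[i])
  pivots <- lapply(pivots, as.integer)
  for (nm in names(pivots)) {
    if (!nm %in% names(ranges)) stop("pivot for unknown segment: ", nm)
    r <- ranges[[nm]]
    if (pivots[[nm]] <= r[1] || pivots[[nm]] >= r[2])
      stop("pivot for ", nm, " must lie strictly inside (", r[1], ",", r[2], ")")
  }
  anchors <- lapply(bw_anchors, function(a) {
    a <- as.integer(a)
    if (length(a) == 1) a <- c(a, 50L)
    if (length(a) != 2) stop("a BW anchor is residue or c(residue, position)")
    a
  })
  structure(list(segments = ranges, pivots = pivots, bw_anchors = anchors),
            class = "segment_definition")
}

#' @export
print.segment_definition <- function(x, ...) {
  cat("<segment_definition>", length(x$segments), "segments,",
      length(x$pivots), "pivot(s),", length(x$bw_anchors), "BW anchor(s)\n")
  for (nm in names(x$segments)) {
    r <- x$segments[[nm]]
    piv <- if (nm %in% names(x$pivots)) paste0("  pivot ", x$pivots[[nm]]) else ""
    cat(sprintf("  %-8s %4d-%-4d%s\n", nm, r[1], r[2], piv))
  }
  invisible(x)
}

#' Read a segment definition from YAML
#'
#' Expected layout: a \code{segments} map of \code{name: [first, last]}, an
#' optional \code{pivots} map, and an optional \code{bw_anchors} map of
#' \code{helix: residue} or \code{helix: [residue, position]}.
#'
#' @param path YAML file
#' @return \code{segment_definition}
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$segments)) stop("segment YAML must contain a 'segments' map")
  segment_definition(y$segments,
                     pivots = if (is.null(y$pivots)) list() else y$pivots,
                     bw_anchors = if (is.null(y$bw_anchors)) list() else y$bw_anchors)
}

#' Write a segment definition to YAML
#' @param x \code{segment_definition}
#' @param path output file
#' @return invisibly, the path
#' @export
write_segments <- function(x, path) {
  yaml::write_yaml(list(segments = x$segments, pivots = x$pivots,
                        bw_anchors = x$bw_anchors), path)
  invisible(path)
}

#' Packaged CB1 segment definition
#'
#' Transmembrane ranges, pivot prolines (P358 in TM6, P394 in TM7) and BW
#' anchors (D163 = 2.50, S203 = 3.39, D390 = 7.46) for the human cannabinoid
#' receptor 1.  The TM ranges are approximate reconstructions and are marked
#' as such in the packaged YAML; anchors and pivots are literature residues.
#'
#' @return \code{segment_definition}
#' @export
cb1_segments <- function() {
  read_segments(system.file("extdata", "cb1_segments.yaml",
                            package = "helixnet", mustWork = TRUE))
}

#' Ballesteros-Weinstein label
#'
#' @param helix_index helix number 1-8
#' @param position the two-digit generic position (the ".NN" part)
#' @return object of class \code{bw_label}; its \code{format} method renders
#'   "H.NN"
#' @export
bw_label <- function(helix_index, position) {
  helix_index <- as.integer(helix_index); position <- as.integer(position)
  if (is.na(helix_index) || helix_index < 1 || helix_index > 8)
    stop("helix index must be 1-8")
  if (is.na(position) || position < 1 || position > 99)
    stop("BW position must be 1-99")
  structure(list(helix_index = helix_index, position = position),
            class = "bw_label")
}

#' @export
format.bw_label <- function(x, ...) sprintf("%d.%02d", x$helix_index, x$position)

#' @export
print.bw_label <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Numeric form of a BW label
#'
#' "2.63" becomes 2.63: helix index plus position/100.  Useful for reporting.
#' @param x \code{bw_label}
#' @return numeric scalar
#' @export
bw_numeric <- function(x) x$helix_index + x$position / 100

bw_anchor_for <- function(definition, helix_index) {
  key <- as.character(helix_index)
  if (!key %in% names(definition$bw_anchors))
    stop("no BW anchor defined for helix ", helix_index)
  definition$bw_anchors[[key]]
}

helix_range_for <- function(definition, helix_index) {
  # helix segments are named TM<h>; split compartments TM<h>-1 / TM<h>-2
  nm <- paste0("TM", helix_index)
  if (nm %in% names(definition$segments)) return(definition$segments[[nm]])
  parts <- grep(paste0("^TM", helix_index, "-"), names(definition$segments), value = TRUE)
  if (length(parts)) {
    r <- range(unlist(definition$segments[parts]))
    return(c(r[1], r[2]))
  }
  NULL
}

#' Map a Ballesteros-Weinstein label to an author residue number
#'
#' Pure offset arithmetic from the helix anchor: the anchor residue carries
#' its anchored position (x.50 by default), and residue numbers change in
#' lock-step with generic positions along the helix.
#'
#' @param label \code{bw_label}
#' @param definition \code{segment_definition} carrying \code{bw_anchors}
#' @return integer residue number
#' @export
bw_to_residue <- function(label, definition) {
  stopifnot(inherits(label, "bw_label"))
  anchor <- bw_anchor_for(definition, label$helix_index)
  res <- anchor[1] + (label$position - anchor[2])
  rng <- helix_range_for(definition, label$helix_index)
  if (!is.null(rng) && (res < rng[1] || res > rng[2]))
    stop(sprintf("BW %s maps to residue %d, outside helix range %d-%d",
                 format(label), res, rng[1], rng[2]))
  as.integer(res)
}

#' Map an author residue number to its Ballesteros-Weinstein label
#'
#' Inverse of \code{\link{bw_to_residue}} under the same pure-offset
#' convention.
#'
#' @param residue_number author residue number
#' @param helix_index helix the residue belongs to
#' @param definition \code{segment_definition}
#' @return \code{bw_label}
#' @export
residue_to_bw <- function(residue_number, helix_index, definition) {
  anchor <- bw_anchor_for(definition, helix_index)
  rng <- helix_range_for(definition, helix_index)
  if (!is.null(rng) && (residue_number < rng[1] || residue_number > rng[2]))
    stop(sprintf("residue %d outside helix %d range %d-%d",
                 residue_number, helix_index, rng[1], rng[2]))
  pos <- anchor[2] + (residue_number - anchor[1])
  bw_label(helix_index, pos)
}

#' Split a segment at its pivot residue
#'
#' The pivot (typically a kink proline) starts the second compartment:
#' sub-segment 1 is \code{[first, pivot - 1]}, sub-segment 2 is
#' \code{[pivot, last]}.  Returned names append "-1" / "-2" to the segment
#' name.
#'
#' @param segment segment name
#' @param definition \code{segment_definition} with a pivot for that segment
#' @return named list of two \code{c(first, last)} ranges
#' @export
split_at_pivot <- function(segment, definition) {
  if (!segment %in% names(definition$segments))
    stop("unknown segment: ", segment)
  if (!segment %in% names(definition$pivots))
    stop("segment ", segment, " has no declared pivot")
  r <- definition$segments[[segment]]
  p <- definition$pivots[[segment]]
  out <- list(c(r[1], p - 1L), c(p, r[2]))
  names(out) <- paste0(segment, c("-1", "-2"))
  out
}

#' Reporting segments: pivoted helices replaced by their compartments
#'
#' @param definition \code{segment_definition}
#' @param tm_only if TRUE keep only TM segments (names starting "TM")
#' @return named list of ranges, with each pivoted segment expanded into its
#'   "-1"/"-2" compartments
#' @export
reporting_segments <- function(definition, tm_only = FALSE) {
  out <- list()
  for (nm in names(definition$segments)) {
    if (tm_only && !grepl("^TM", nm)) next
    if (nm %in% names(definition$pivots)) {
      out <- c(out, split_at_pivot(nm, definition))
    } else {
      out[[nm]] <- definition$segments[[nm]]
    }
  }
  out
}
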
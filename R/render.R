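# Figures are written as hand-generated SVG: text-only, deterministic, and
# the drawn quantities (ribbon/edge stroke widths) are recoverable by parsing
# the file, so plots can be verified against their sibling CSVs.

svg_header <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>')
}

num <- function(x) formatC(x, format = "f", digits = 3)

#' Render a group energy matrix as a chord-style diagram
#'
#' Groups are arranged on a circle; each off-diagonal group pair with
#' non-zero energy is drawn as a quadratic ribbon whose stroke width is
#' proportional to |energy| (class "ribbon" in the SVG, so widths can be
#' parsed back).  Attractive (negative) energies are blue, repulsive red.
#'
#' @param gm \code{group_energy}
#' @param out output SVG path
#' @param width_per_kcal stroke width per kcal/mol (default 2)
#' @param max_width clip for very strong pairs (default 30)
#' @return invisibly, the path
#' @export
render_group_chord <- function(gm, out, width_per_kcal = 2, max_width = 30) {
  stopifnot(inherits(gm, "group_energy"))
  m <- gm$energy
  ng <- length(gm$groups)
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  if (nrow(ut) == 0) stop("nothing to plot: all group pair energies are zero")
  size <- 520; cx <- size / 2; cy <- size / 2; R <- 190
  ang <- 2 * pi * (seq_len(ng) - 1) / ng - pi / 2
  px <- cx + R * cos(ang); py <- cy + R * sin(ang)
  lines <- svg_header(size, size)
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    w <- min(abs(m[i, j]) * width_per_kcal, max_width)
    col <- if (m[i, j] < 0) "#2166ac" else "#b2182b"
    lines <- c(lines, sprintf(
      '<path class="ribbon" d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="0.65" data-energy="%s"/>',
      num(px[i]), num(py[i]), num(cx), num(cy), num(px[j]), num(py[j]),
      col, num(w), num(m[i, j])))
  }
  for (g in seq_len(ng)) {
    lines <- c(lines,
               sprintf('<circle class="group" cx="%s" cy="%s" r="8" fill="#444"/>',
                       num(px[g]), num(py[g])),
               sprintf('<text x="%s" y="%s" font-size="13" text-anchor="middle">%s</text>',
                       num(cx + (R + 22) * cos(ang[g])),
                       num(cy + (R + 22) * sin(ang[g]) + 4), gm$groups[g]))
  }
  writeLines(c(lines, "</svg>"), out)
  invisible(out)
}

#' Render an energy or difference network on the structure
#'
#' A 2D (x, y) projection with residue nodes at C-alpha positions and one
#' edge per unmasked pair with |energy| at or above the threshold; edge
#' stroke width is proportional to |energy|.  For an \code{avg_energy},
#' attractive edges are blue and repulsive red; for a \code{diff_network},
#' edges are coloured by their sign classification (attractive-lost blue,
#' attractive-gained green, repulsive-gained orange, repulsive-lost
#' magenta).
#'
#' @param x \code{helix_structure} providing C-alpha coordinates
#' @param mat \code{avg_energy} or \code{diff_network}
#' @param out output SVG path
#' @param threshold kcal/mol on |energy| (default 0.5)
#' @param width_per_kcal stroke width per kcal/mol (default 3)
#' @param max_width clip (default 24)
#' @return invisibly, the path
#' @export
render_structure_network <- function(x, mat, out, threshold = 0.5,
                                     width_per_kcal = 3, max_width = 24) {
  is_diff <- inherits(mat, "diff_network")
  m <- if (is_diff) mat$delta else mat$mean
  cls <- if (is_diff) classify_diff(mat) else NULL
  ca <- atom_indices(x, atom_names = "CA")
  rt <- residue_table(x)
  key <- paste(rt$chain_id, rt$residue_number)
  want <- paste(mat$residues$chain_id, mat$residues$residue_number)
  pos_idx <- ca[match(want, key)]
  if (anyNA(pos_idx))
    stop("residue(s) in the matrix have no C-alpha in the structure: ",
         paste(utils::head(want[is.na(pos_idx)], 5), collapse = ", "))
  xy <- x$coords[pos_idx, 1:2, drop = FALSE]
  size <- 600; pad <- 40
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  scale <- (size - 2 * pad) / max(diff(rngx), diff(rngy), 1e-6)
  sx <- pad + (xy[, 1] - rngx[1]) * scale
  sy <- size - pad - (xy[, 2] - rngy[1]) * scale
  ut <- which(upper.tri(m) & !mat$mask & abs(m) >= threshold, arr.ind = TRUE)
  palette <- c("attractive-lost" = "#2166ac", "attractive-gained" = "#1a9850",
               "repulsive-gained" = "#e08214", "repulsive-lost" = "#c51b7d",
               "unchanged" = "#999999")
  lines <- svg_header(size, size)
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    w <- min(abs(m[i, j]) * width_per_kcal, max_width)
    col <- if (is_diff) palette[[cls[i, j]]]
           else if (m[i, j] < 0) "#2166ac" else "#b2182b"
    cat_cls <- if (is_diff) cls[i, j] else if (m[i, j] < 0) "attractive" else "repulsive"
    lines <- c(lines, sprintf(
      '<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="0.8" data-energy="%s" data-class="%s"/>',
      num(sx[i]), num(sy[i]), num(sx[j]), num(sy[j]), col, num(w),
      num(m[i, j]), cat_cls))
  }
  for (i in seq_len(nrow(xy)))
    lines <- c(lines,
               sprintf('<circle class="node" cx="%s" cy="%s" r="4" fill="#333" data-residue="%d"/>',
                       num(sx[i]), num(sy[i]), mat$residues$residue_number[i]))
  writeLines(c(lines, "</svg>"), out)
  invisible(out)
}
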
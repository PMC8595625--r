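# rotation matrices (right-handed, degrees)
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# minimal polar/charged side-chain geometries beyond C-beta: idealized
# extended chains along the outward direction u with tangential branching t,
# relative to C-alpha (Angstrom).  Apolar residues stop at C-beta.
side_chain_atoms <- function(code, u, tang) {
  mk <- function(names, au, bt) {
    list(names = names,
         xyz = do.call(rbind, Map(function(a, b) a * u + b * tang, au, bt)))
  }
  switch(code,
    S = mk("OG", 2.93, 0),
    D = mk(c("CG", "OD1", "OD2"), c(2.9, 3.55, 3.55), c(0, 1.1, -1.1)),
    N = mk(c("CG", "OD1", "ND2"), c(2.9, 3.55, 3.55), c(0, 1.1, -1.1)),
    E = mk(c("CG", "CD", "OE1", "OE2"), c(2.9, 4.2, 4.85, 4.85), c(0, 0, 1.1, -1.1)),
    Q = mk(c("CG", "CD", "OE1", "NE2"), c(2.9, 4.2, 4.85, 4.85), c(0, 0, 1.1, -1.1)),
    K = mk(c("CG", "CD", "CE", "NZ"), c(2.9, 4.2, 5.5, 6.6), c(0, 0, 0, 0)),
    R = mk(c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
           c(2.9, 4.2, 5.5, 6.8, 7.45, 7.45), c(0, 0, 0, 0, 1.1, -1.1)),
    list(names = character(0), xyz = NULL))
}

#' Generate an ideal alpha-helix
#'
#' Backbone atoms (N, CA, C, O) are placed on a continuous helical curve with
#' the canonical alpha-helix parameters (1.5 Angstrom rise and 100 degrees
#' twist per residue, 2.3 Angstrom C-alpha radius); N and C sit at fractional
#' residue offsets chosen so bond lengths are ~1.5 Angstrom, O extends from C
#' roughly along the helix axis, and C-beta points radially outward for
#' non-glycine residues.  The helix is built along +Z, centred on its axis
#' midpoint, then rotated by tilt (about Y) and azimuth (about Z):
#' the final axis direction is
#' (sin(tilt) cos(azimuth), sin(tilt) sin(azimuth), cos(tilt)).
#'
#' @param n_residues number of residues (>= 6)
#' @param rise Angstrom per residue (default 1.5)
#' @param twist degrees per residue (default 100)
#' @param radius C-alpha helix radius, Angstrom (default 2.3)
#' @param tilt degrees from +Z, in [0, 180]
#' @param azimuth degrees about Z
#' @param sequence 1-letter codes (recycled; default all-alanine)
#' @param start_residue first author residue number
#' @param chain chain id
#' @param origin 3-vector added to all coordinates
#' @param label structure label
#' @return \code{helix_structure}
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                             tilt = 0, azimuth = 0, sequence = "A",
                             start_residue = 1, chain = "A", origin = c(0, 0, 0),
                             label = "ideal-helix") {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 6)
    stop("an ideal helix needs at least 6 residues")
  if (tilt < 0 || tilt > 180) stop("tilt must lie in [0, 180] degrees")
  seq1 <- strsplit(paste(rep(sequence, length.out = n_residues), collapse = ""),
                   "")[[1]][seq_len(n_residues)]
  res3 <- unname(AA3[seq1])
  if (anyNA(res3)) stop("unknown 1-letter code(s) in sequence")
  omega <- twist * pi / 180
  curve <- function(t) cbind(radius * cos(omega * t), radius * sin(omega * t),
                             rise * t)
  atoms <- list(); coords <- list()
  for (i in seq_len(n_residues)) {
    t0 <- i - 1
    n_xyz <- curve(t0 - 0.35)
    ca_xyz <- curve(t0)
    c_xyz <- curve(t0 + 0.35)
    # carbonyl O: off C, mostly along the helix axis (i -> i+4 ladder)
    radial_c <- c(cos(omega * (t0 + 0.35)), sin(omega * (t0 + 0.35)), 0)
    o_dir <- 0.40 * radial_c + c(0, 0, 0.92)
    o_xyz <- c_xyz + 1.23 * o_dir / sqrt(sum(o_dir^2))
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(n_xyz, ca_xyz, c_xyz, o_xyz)
    if (res3[i] != "GLY") {
      radial_ca <- c(cos(omega * t0), sin(omega * t0), 0)
      cb_dir <- 0.94 * radial_ca + c(0, 0, -0.34)
      u <- cb_dir / sqrt(sum(cb_dir^2))          # outward side-chain direction
      tang <- c(-sin(omega * t0), cos(omega * t0), 0)
      side <- side_chain_atoms(seq1[i], u, tang)
      xyz <- rbind(xyz, sweep(rbind(1.53 * u, side$xyz), 2, as.numeric(ca_xyz), `+`))
      nm <- c(nm, "CB", side$names)
    }
    nm <- unname(nm)
    atoms[[i]] <- data.frame(atom_name = nm,
                             residue_number = start_residue + i - 1L,
                             residue_name = res3[i], chain_id = chain,
                             element = substr(nm, 1, 1),
                             stringsAsFactors = FALSE)
    coords[[i]] <- xyz
  }
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  xyz[, 3] <- xyz[, 3] - rise * (n_residues - 1) / 2   # centre axis midpoint at z=0
  R <- rot_z(azimuth) %*% rot_y(tilt)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, origin, `+`)
  new_structure(atoms, xyz, label = label)
}

#' Generate a 7TM-like helix bundle with a segment definition
#'
#' Helices are arranged on a circle with alternating N-to-C direction
#' (odd helices run up, even run down, as TM helices do), each given its own
#' residue range separated by a loop-sized numbering gap.  The matching
#' \code{segment_definition} is attached as attribute \code{"definition"}.
#'
#' @param n_helices number of helices (>= 2; default 7)
#' @param n_residues residues per helix (default 24, a typical TM span; with
#'   the default 100-degree twist this also places the two endpoint windows a
#'   whole number of helical turns apart, so the 11-atom endpoint rule's
#'   discretization bias nearly cancels)
#' @param bundle_radius circle radius for helix axes, Angstrom (default 15)
#' @param tilts per-helix tilt in degrees for odd (up) helices; even helices
#'   get 180 - tilt (recycled; default 10)
#' @param loop_gap residue-numbering gap between helices (default 6)
#' @param start_residue first residue number of helix 1
#' @param pivot_helices helix indices given a mid-helix pivot (default none)
#' @param sequence 1-letter sequence per helix, recycled across helices
#'   (default poly-alanine)
#' @return \code{helix_structure} with attribute \code{"definition"}
#' @export
make_bundle <- function(n_helices = 7, n_residues = 24, bundle_radius = 15,
                        tilts = 10, loop_gap = 6, start_residue = 1,
                        pivot_helices = integer(0), sequence = "A") {
  if (n_helices < 2) stop("a bundle needs at least 2 helices")
  tilts <- rep(tilts, length.out = n_helices)
  seqs <- rep(sequence, length.out = n_helices)
  atoms <- list(); coords <- list(); segs <- list(); pivots <- list()
  res0 <- as.integer(start_residue)
  for (h in seq_len(n_helices)) {
    phi <- 360 * (h - 1) / n_helices
    up <- h %% 2 == 1
    tilt_h <- if (up) tilts[h] else 180 - tilts[h]
    centre <- c(bundle_radius * cos(phi * pi / 180),
                bundle_radius * sin(phi * pi / 180), 0)
    hx <- make_ideal_helix(n_residues, tilt = tilt_h, azimuth = phi + 180,
                           start_residue = res0, origin = centre,
                           sequence = seqs[h], label = paste0("TM", h))
    atoms[[h]] <- hx$atoms
    coords[[h]] <- hx$coords
    segs[[paste0("TM", h)]] <- c(res0, res0 + n_residues - 1L)
    if (h %in% pivot_helices)
      pivots[[paste0("TM", h)]] <- res0 + n_residues %/% 2
    res0 <- res0 + n_residues + as.integer(loop_gap)
  }
  out <- new_structure(do.call(rbind, atoms), do.call(rbind, coords),
                       label = "7tm-bundle")
  # clash guard between distinct helices
  d <- dist_matrix(out$coords)
  seg_id <- rep(seq_len(n_helices), vapply(atoms, nrow, integer(1)))
  inter <- d[outer(seg_id, seg_id, `!=`)]
  if (min(inter) <= 1.5)
    stop(sprintf("helix placement clashes (min inter-helix distance %.2f A); increase bundle_radius",
                 min(inter)))
  anchors <- as.list(vapply(segs, function(r) as.integer(r[1] + (r[2] - r[1]) %/% 2),
                            integer(1)))
  names(anchors) <- as.character(seq_len(n_helices))
  attr(out, "definition") <- segment_definition(segs, pivots = pivots,
                                                bw_anchors = anchors)
  out
}

#' Generate a noisy trajectory with optional planted rigid motions
#'
#' Frames are the input coordinates plus i.i.d. isotropic Gaussian noise of
#' standard deviation \code{sigma} per coordinate.  A motion schedule plants
#' rigid-body perturbations of named segments: from \code{start_frame} on,
#' the segment's atoms are rotated by \code{tilt} degrees about an axis
#' perpendicular to Z through the segment centroid and translated by
#' \code{shift}.
#'
#' @param x \code{helix_structure}
#' @param sigma noise standard deviation per coordinate, Angstrom
#' @param n_frames number of frames
#' @param seed RNG seed (required for determinism)
#' @param motions optional list of lists with fields \code{segment},
#'   \code{start_frame}, \code{tilt} (degrees, default 0), \code{shift}
#'   (3-vector, default 0)
#' @param definition \code{segment_definition} resolving motion segment
#'   names (defaults to the structure's \code{"definition"} attribute)
#' @return \code{helix_trajectory}
#' @export
make_noisy_trajectory <- function(x, sigma = 0.1, n_frames = 100, seed = 1,
                                  motions = NULL, definition = attr(x, "definition")) {
  stopifnot(sigma >= 0, n_frames >= 1)
  set.seed(seed)
  base <- as.numeric(t(x$coords))
  na <- n_atoms(x)
  xyz <- matrix(rep(base, each = n_frames), nrow = n_frames) +
    if (sigma > 0) matrix(stats::rnorm(n_frames * 3 * na, sd = sigma),
                          nrow = n_frames) else 0
  if (!is.null(motions)) {
    if (is.null(definition))
      stop("motions need a segment_definition to resolve segment names")
    for (mo in motions) {
      rng <- segment_range(mo$segment, definition)
      idx <- atom_indices(x, residues = seq(rng[1], rng[2]))
      cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
      centroid <- colMeans(x$coords[idx, , drop = FALSE])
      R <- rot_y(if (is.null(mo$tilt)) 0 else mo$tilt)
      shift <- if (is.null(mo$shift)) c(0, 0, 0) else mo$shift
      for (f in seq(mo$start_frame, n_frames)) {
        co <- matrix(xyz[f, cols], ncol = 3, byrow = TRUE)
        co <- sweep(sweep(co, 2, centroid) %*% t(R), 2, centroid + shift, `+`)
        xyz[f, cols] <- as.numeric(t(co))
      }
    }
  }
  new_trajectory(x, xyz)
}

#' Specification for a planted wildtype/mutant energy system
#'
#' @param groups named integer vector: group name -> number of residues
#' @param baseline_pairs data.frame (res_i, res_j, energy) of wildtype pair
#'   energies, kcal/mol
#' @param mutant_deltas data.frame (res_i, res_j, delta) added to the mutant
#' @param replicate_noise_sd Gaussian noise per replicate entry, kcal/mol
#' @param n_replicates replicates per condition
#' @param seed RNG seed
#' @return list of class \code{planted_energy_spec}
#' @export
planted_energy_spec <- function(groups = c(A = 5, B = 5),
                                baseline_pairs = NULL, mutant_deltas = NULL,
                                replicate_noise_sd = 0.1, n_replicates = 3,
                                seed = 1) {
  stopifnot(replicate_noise_sd >= 0, n_replicates >= 1)
  structure(list(groups = groups, baseline_pairs = baseline_pairs,
                 mutant_deltas = mutant_deltas,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = n_replicates, seed = seed),
            class = "planted_energy_spec")
}

#' Generate paired wildtype/mutant energy matrices with known ground truth
#'
#' Residues are numbered 1..N across the groups in order.  Each replicate is
#' the baseline matrix (plus the planted deltas for the mutant) with
#' symmetric Gaussian noise added to the off-diagonal entries.  The exact
#' planted difference matrix is returned as \code{truth}.
#'
#' @param spec \code{\link{planted_energy_spec}}
#' @return list with \code{wt} and \code{mut} (lists of
#'   \code{pairwise_energy} replicates), \code{truth} (exact delta matrix),
#'   \code{definition} (a \code{segment_definition} over the groups), and
#'   \code{residues}
#' @export
make_planted_energy_system <- function(spec) {
  stopifnot(inherits(spec, "planted_energy_spec"))
  set.seed(spec$seed)
  sizes <- spec$groups
  nres <- sum(sizes)
  residues <- data.frame(chain_id = "A", residue_number = seq_len(nres),
                         residue_name = "ALA", stringsAsFactors = FALSE)
  ends <- cumsum(sizes)
  segs <- Map(function(e, s) c(e - s + 1L, e), as.integer(ends), as.integer(sizes))
  names(segs) <- names(sizes)
  base <- matrix(0, nres, nres)
  fill <- function(m, df, col) {
    if (!is.null(df)) for (k in seq_len(nrow(df))) {
      i <- df$res_i[k]; j <- df$res_j[k]
      if (i > nres || j > nres) stop("planted pair references residue beyond the system")
      m[i, j] <- m[i, j] + df[[col]][k]
      m[j, i] <- m[i, j]
    }
    m
  }
  base <- fill(base, spec$baseline_pairs, "energy")
  delta <- fill(matrix(0, nres, nres), spec$mutant_deltas, "delta")
  mask <- matrix(FALSE, nres, nres); diag(mask) <- TRUE
  wrap <- function(m, rep_id, cond) {
    structure(list(residues = residues, coulomb = m, vdw = 0 * m, gb = 0 * m,
                   total = m,
                   self = data.frame(coulomb = rep(0, nres), vdw = 0, gb = 0, total = 0),
                   mask = mask,
                   meta = list(frames_averaged = NA_integer_,
                               replicate_id = rep_id, condition = cond,
                               exclusion_window = NA_integer_)),
              class = "pairwise_energy")
  }
  noisy <- function(m) {
    e <- matrix(0, nres, nres)
    up <- upper.tri(e)
    e[up] <- stats::rnorm(sum(up), sd = spec$replicate_noise_sd)
    e <- e + t(e)
    m + e
  }
  wt <- lapply(seq_len(spec$n_replicates), function(r) wrap(noisy(base), r, "wt"))
  mut <- lapply(seq_len(spec$n_replicates), function(r) wrap(noisy(base + delta), r, "mut"))
  list(wt = wt, mut = mut, truth = delta, residues = residues,
       definition = segment_definition(segs))
}

#' Minimal two-residue contact fixture
#'
#' Builds a two-residue structure realizing a requested hydrogen-bond or
#' salt-bridge geometry exactly: for \code{"hbond"}, a serine OG-HG donor and
#' a backbone carbonyl O acceptor with the requested donor-acceptor distance
#' and D-H...A angle; for \code{"saltbridge"}, an aspartate carboxylate and a
#' lysine NZ at the requested minimum distance.
#'
#' @param kind "hbond" or "saltbridge"
#' @param distance donor-acceptor (or anion-cation) heavy-atom distance,
#'   Angstrom
#' @param angle D-H...A angle in degrees (hbond only; default 165)
#' @return \code{helix_structure}
#' @export
make_contact_fixture <- function(kind = c("hbond", "saltbridge"),
                                 distance = 2.9, angle = 165) {
  kind <- match.arg(kind)
  if (distance <= 0) stop("distance must be positive")
  bb <- function(resno, resname, origin, extra_names = character(),
                 extra_xyz = NULL) {
    nm <- c("N", "CA", "C", "O", extra_names)
    xyz <- rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.3, 0.6, 0), c(1.4, 1.83, 0))
    if (!is.null(extra_xyz)) xyz <- rbind(xyz, extra_xyz)
    xyz <- sweep(xyz, 2, origin, `+`)
    list(atoms = data.frame(atom_name = nm, residue_number = resno,
                            residue_name = resname, chain_id = "A",
                            element = substr(nm, 1, 1),
                            stringsAsFactors = FALSE),
         xyz = xyz)
  }
  if (kind == "hbond") {
    if (angle <= 0 || angle > 180) stop("hbond angle must be in (0, 180]")
    # donor OG at origin, acceptor O at (distance, 0, 0); place HG so the
    # OG-HG...O angle at HG equals `angle` (solved on the OG-centred circle)
    doh <- 0.96
    f <- function(phi) {
      h <- doh * c(cos(phi), sin(phi), 0)
      angle_deg(c(0, 0, 0), h, c(distance, 0, 0)) - angle
    }
    if (f(0) < 0) stop("infeasible hbond geometry: requested angle unreachable")
    phi <- stats::uniroot(f, c(0, pi - 1e-9), tol = 1e-12)$root
    hg <- doh * c(cos(phi), sin(phi), 0)
    don <- bb(1, "SER", c(-6, 0, 0),
              extra_names = c("CB", "OG", "HG"),
              extra_xyz = rbind(c(5.0, -1.0, 0), c(6, 0, 0), c(6, 0, 0) + hg))
    acc <- bb(2, "ALA", c(distance + 2.5, -3.5, 0), extra_names = "CB",
              extra_xyz = rbind(c(-0.5, -1.3, 0)))
    # overwrite acceptor backbone O to sit exactly at (distance, 0, 0)
    acc$xyz[4, ] <- c(distance, 0, 0)
  } else {
    don <- bb(1, "ASP", c(-7, 0, 0),
              extra_names = c("CB", "CG", "OD1", "OD2"),
              extra_xyz = rbind(c(5.3, -1.1, 0), c(6.3, -0.4, 0),
                                c(7, 0, 0), c(6.5, -1.6, 0)))
    acc <- bb(2, "LYS", c(distance + 7, 0, 0),
              extra_names = c("CB", "CG", "CD", "CE", "NZ"),
              extra_xyz = rbind(c(-5.3, -1.1, 0), c(-5.9, -0.5, 0),
                                c(-6.4, -1.2, 0), c(-6.8, -0.4, 0), c(-7, 0, 0)))
  }
  new_structure(rbind(don$atoms, acc$atoms), rbind(don$xyz, acc$xyz),
                label = paste0("contact-", kind))
}
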
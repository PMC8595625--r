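#' Rigid-body align a trajectory to a reference structure
#'
#' Least-squares (Kabsch) superposition of every frame onto the reference over
#' a selected atom set; all atoms are moved by the fitted transform.  The
#' default selection is the C-alpha atoms of all TM residues (loops excluded)
#' when a segment definition is supplied, otherwise all C-alpha atoms.
#'
#' @param traj \code{helix_trajectory}
#' @param ref \code{helix_structure}, same topology
#' @param selection integer atom indices to fit over, or NULL for the default
#' @param definition optional \code{segment_definition} used to build the
#'   default TM C-alpha selection
#' @return aligned \code{helix_trajectory}
#' @export
align_to_reference <- function(traj, ref, selection = NULL, definition = NULL) {
  if (n_atoms(ref) != n_atoms(traj$topology))
    stop("reference and trajectory topologies differ in atom count")
  if (is.null(selection)) {
    res <- NULL
    if (!is.null(definition)) {
      tm <- grep("^TM", names(definition$segments), value = TRUE)
      res <- unlist(lapply(definition$segments[tm],
                           function(r) seq(r[1], r[2])), use.names = FALSE)
    }
    selection <- atom_indices(ref, residues = res, atom_names = "CA")
  }
  if (length(selection) < 3)
    stop("superposition needs at least 3 selected atoms, got ", length(selection))
  fixed <- as.numeric(t(ref$coords))
  inds <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = traj$xyz,
                           fixed.inds = inds, mobile.inds = inds)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  new_trajectory(traj$topology, fitted, traj$frame_interval)
}

# indices of one backbone atom; errors if absent
one_atom <- function(x, resno, name) {
  i <- atom_indices(x, residues = resno, atom_names = name)
  if (length(i) != 1)
    stop("expected exactly one ", name, " atom in residue ", resno,
         ", found ", length(i))
  i
}

#' Endpoint atom set of a helix terminus
#'
#' Implements the 11-backbone-atom endpoint rule: skip one gap residue at the
#' extreme end of the helix range, take the C, CA, N atoms of the next four
#' residues (one helical turn, 12 atoms), then drop the single innermost
#' backbone atom - the one covalently closest to the helix middle (the C atom
#' of the innermost window residue at the N-terminal end, the N atom at the
#' C-terminal end).  The endpoint is the unweighted mean of the 11 positions.
#'
#' @param x \code{helix_structure}
#' @param segment segment name (may be a "-1"/"-2" compartment name)
#' @param terminus "N" or "C"
#' @param definition \code{segment_definition}
#' @param coords optional coordinate override (n_atoms x 3), e.g. one frame
#' @return list with \code{atom_set} (data.frame residue_number, atom_name),
#'   \code{indices}, and \code{point} (3-vector)
#' @export
endpoint_atoms <- function(x, segment, terminus = c("N", "C"), definition,
                           coords = NULL) {
  terminus <- match.arg(terminus)
  rng <- segment_range(segment, definition)
  if (rng[2] - rng[1] + 1 < 6)
    stop("segment ", segment, " has fewer than 6 residues; endpoint rule needs",
         " a gap residue plus a 4-residue window")
  if (terminus == "N") {
    window <- seq(rng[1] + 1, rng[1] + 4)  # gap residue rng[1] skipped
    inner_res <- rng[1] + 4
    drop_name <- "C"                       # points toward the helix middle
  } else {
    window <- seq(rng[2] - 4, rng[2] - 1)  # gap residue rng[2] skipped
    inner_res <- rng[2] - 4
    drop_name <- "N"
  }
  set <- expand.grid(atom_name = c("N", "CA", "C"), residue_number = window,
                     stringsAsFactors = FALSE)
  drop <- set$residue_number == inner_res & set$atom_name == drop_name
  set <- set[!drop, c("residue_number", "atom_name")]
  idx <- mapply(function(r, n) one_atom(x, r, n),
                set$residue_number, set$atom_name)
  if (is.null(coords)) coords <- x$coords
  list(atom_set = set, indices = as.integer(idx),
       point = colMeans(coords[idx, , drop = FALSE]))
}

# resolve a segment or split-compartment name to a residue range
segment_range <- function(segment, definition) {
  if (segment %in% names(definition$segments))
    return(definition$segments[[segment]])
  m <- regmatches(segment, regexec("^(.*)-([12])$", segment))[[1]]
  if (length(m) == 3 && m[2] %in% names(definition$segments)) {
    parts <- split_at_pivot(m[2], definition)
    return(parts[[segment]])
  }
  stop("unknown segment: ", segment)
}

#' Helix vector of a segment
#'
#' N- and C-terminal endpoints by \code{\link{endpoint_atoms}}; the direction
#' is the unit vector from the N endpoint to the C endpoint.
#'
#' @inheritParams endpoint_atoms
#' @return list with \code{segment}, \code{n_point}, \code{c_point},
#'   \code{direction}
#' @export
helix_vector <- function(x, segment, definition, coords = NULL) {
  n_pt <- endpoint_atoms(x, segment, "N", definition, coords)$point
  c_pt <- endpoint_atoms(x, segment, "C", definition, coords)$point
  v <- c_pt - n_pt
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("degenerate helix vector (endpoints coincide)")
  list(segment = segment, n_point = n_pt, c_point = c_pt, direction = v / len)
}

#' Tilt angle of a helix vector against the membrane normal
#'
#' The membrane normal is the Z axis; the angle is
#' \code{acos(direction . z)} in degrees, in [0, 180] so that helix
#' directionality (alternating N-to-C orientation across a 7TM bundle) is
#' preserved.
#'
#' @param vec a helix vector from \code{\link{helix_vector}}, or a bare
#'   3-vector
#' @return angle in degrees
#' @export
helix_angle <- function(vec) {
  d <- if (is.list(vec)) vec$direction else vec
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("degenerate (zero-length) helix vector")
  acos(max(-1, min(1, d[3] / len))) * 180 / pi
}

#' Per-segment RMSD without refitting
#'
#' RMSD over the segment's C, CA, O and N backbone atoms with no
#' superposition, so rigid shifts and tilts of the helix contribute to the
#' value.  The frame is assumed already globally aligned.
#'
#' @param coords frame coordinates (n_atoms x 3), atom order of \code{ref}
#' @param ref reference \code{helix_structure}
#' @param segment segment name (or compartment name)
#' @param definition \code{segment_definition}
#' @return RMSD in Angstrom
#' @export
segment_rmsd_nofit <- function(coords, ref, segment, definition) {
  rng <- segment_range(segment, definition)
  idx <- atom_indices(ref, residues = seq(rng[1], rng[2]),
                      atom_names = c("C", "CA", "O", "N"))
  if (!length(idx)) stop("no backbone atoms found for segment ", segment)
  d <- coords[idx, , drop = FALSE] - ref$coords[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each residue's C-alpha (configurable atom) about its time-average
#' position, over an aligned trajectory.
#'
#' @param traj aligned \code{helix_trajectory} with at least 2 frames
#' @param atom_name atom used per residue (default "CA")
#' @param residues optional residue subset
#' @return data.frame with \code{chain_id}, \code{residue_number},
#'   \code{rmsf} (Angstrom)
#' @export
rmsf_profile <- function(traj, atom_name = "CA", residues = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  top <- traj$topology
  idx <- atom_indices(top, residues = residues, atom_names = atom_name)
  if (!length(idx)) stop("no ", atom_name, " atoms selected")
  out <- top$atoms[idx, c("chain_id", "residue_number")]
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  sub <- traj$xyz[, cols, drop = FALSE]
  mu <- colMeans(sub)
  dev2 <- sweep(sub, 2, mu)^2
  per_coord <- colMeans(dev2)                       # time-variance per coordinate
  out$rmsf <- sqrt(rowSums(matrix(per_coord, ncol = 3, byrow = TRUE)))
  rownames(out) <- NULL
  out
}

#' Per-frame helix angle and no-fit RMSD series
#'
#' One sample per (frame, segment) over the reporting segments (helices with a
#' declared pivot are replaced by their two compartments).  Per-segment mean
#' angle and RMSD are attached as the \code{"means"} attribute.
#'
#' @param traj aligned \code{helix_trajectory}
#' @param ref reference \code{helix_structure}
#' @param definition \code{segment_definition}
#' @param tm_only restrict to TM segments (default TRUE)
#' @return data.frame with \code{frame_index}, \code{segment},
#'   \code{angle_deg}, \code{rmsd_A}; attribute \code{"means"} holds the
#'   per-segment averages
#' @export
angle_rmsd_series <- function(traj, ref, definition, tm_only = TRUE) {
  segs <- reporting_segments(definition, tm_only = tm_only)
  nf <- n_frames(traj)
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    ang <- vapply(names(segs), function(s)
      helix_angle(helix_vector(ref, s, definition, coords = co)), numeric(1))
    rms <- vapply(names(segs), function(s)
      segment_rmsd_nofit(co, ref, s, definition), numeric(1))
    res[[f]] <- data.frame(frame_index = f, segment = names(segs),
                           angle_deg = unname(ang), rmsd_A = unname(rms),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  means <- aggregate(cbind(angle_deg, rmsd_A) ~ segment, data = out, FUN = mean)
  attr(out, "means") <- means[match(names(segs), means$segment), ]
  out
}
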
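#' Construct a trajectory
#'
#' Frames share the topology's atom order; coordinates are stored as a
#' frames x (3 * n_atoms) matrix (x1,y1,z1,x2,...), the layout bio3d uses.
#'
#' @param topology \code{helix_structure}
#' @param xyz numeric matrix, n_frames x (3 * n_atoms)
#' @param frame_interval optional time between frames (arbitrary units)
#' @return object of class \code{helix_trajectory}
#' @export
new_trajectory <- function(topology, xyz, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "helix_structure"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms(topology))
    stop("frame width ", ncol(xyz), " does not match topology atom count ",
         n_atoms(topology))
  structure(list(topology = topology, xyz = xyz, frame_interval = frame_interval),
            class = "helix_trajectory")
}

#' @export
print.helix_trajectory <- function(x, ...) {
  cat(sprintf("<helix_trajectory> %d frames x %d atoms\n",
              nrow(x$xyz), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames
#' @param traj \code{helix_trajectory}
#' @return integer
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj \code{helix_trajectory}
#' @param i frame index (1-based)
#' @return numeric matrix
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB (extension .pdb) and DCD (.dcd).  Every frame
#' must match the topology's atom count.
#'
#' @param topology \code{helix_structure} giving atom identities and order
#' @param path trajectory file
#' @return \code{helix_trajectory}
#' @export
read_trajectory <- function(topology, path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- as.matrix(xyz)
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    keep <- trimws(pdb$atom$resid) %in% STANDARD_AA
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
    xyz <- xyz[, cols, drop = FALSE]
  } else {
    stop("unsupported trajectory format: .", ext, " (use multi-model PDB or DCD)")
  }
  if (ncol(xyz) != 3 * n_atoms(topology))
    stop("trajectory atom count ", ncol(xyz) / 3,
         " does not match topology atom count ", n_atoms(topology))
  new_trajectory(topology, xyz)
}

#' Write a trajectory as a multi-model PDB
#' @param traj \code{helix_trajectory}
#' @param path output path
#' @return invisibly, the path
#' @export
write_trajectory <- function(traj, path) {
  write_structure(traj$topology, path, xyz = traj$xyz)
  invisible(path)
}
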